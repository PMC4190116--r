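test_that("match_reference ranks species by identity", {
  set.seed(61)
  seq_a <- rand_dna(500)
  seq_b <- substitute_at(seq_a, 30)
  db <- make_refdb(c("Alpha one", "Beta two"), rbcl_seqs = c(seq_a, seq_b))
  hits <- match_reference(seq_a, db, "rbcL")
  expect_equal(hits$species, c("Alpha one", "Beta two"))
  expect_equal(hits$identity_pct[1], 100)
  # query 2 subs from A, 30 from B (up to shared positions)
  q <- substitute_at(seq_a, 2)
  hits <- match_reference(q, db, "rbcL")
  expect_equal(hits$species[1], "Alpha one")
  expect_equal(hits$identity_pct[1], 100 * 498 / 500)
  expect_lt(hits$identity_pct[2], 95)
  expect_error(match_reference(q, db[db$marker == "rbcL", ], "trnH-psbA"),
               "no records")
})

test_that("the congener pattern yields a 100 / 99.6 hit pair", {
  set.seed(62)
  campestre <- rand_dna(500)
  platanoides <- substitute_at(campestre, 2)
  db <- make_refdb(c("Acer campestre", "Acer platanoides"),
                   rbcl_seqs = c(campestre, platanoides))
  hits <- match_reference(campestre, db, "rbcL")
  expect_equal(hits$species, c("Acer campestre", "Acer platanoides"))
  expect_equal(round(hits$identity_pct, 1), c(100, 99.6))
})

test_that("threshold rule: species, genus, ambiguous and unidentifiable", {
  hit <- function(species, id) data.frame(
    species = species, genus = sub("\\s.*", "", species),
    identity_pct = id, marker = "rbcL", stringsAsFactors = FALSE)

  a <- assign_taxonomy(hit("Fagus sylvatica", 100))
  expect_equal(a$call_level, "species")
  expect_equal(a$call_name, "Fagus sylvatica")

  a <- assign_taxonomy(hit(c("Acer campestre", "Acer platanoides"),
                           c(100, 99.6)))
  expect_equal(a$call_level, "genus")
  expect_equal(a$call_name, "Acer sp.")

  a <- assign_taxonomy(hit("Some species", 98.5))
  expect_equal(a$call_level, "unidentifiable")
  expect_equal(a$call_name, "unidentifiable")
  expect_true(flag_for_external_lookup(a))

  a <- assign_taxonomy(hit(c("Cyanus triumfettii", "Saussurea alpina"),
                           c(100, 100)))
  expect_equal(a$call_level, "ambiguous_multi_genus")
  expect_false(flag_for_external_lookup(a))

  # sub-threshold congener does not demote the unique qualifying species
  a <- assign_taxonomy(hit(c("Acer campestre", "Acer platanoides"),
                           c(100, 98.2)))
  expect_equal(a$call_level, "species")

  expect_error(assign_taxonomy(hit(c("B b", "A a"), c(99, 100))), "sorted")
})

test_that("threshold comparison uses the unrounded identity", {
  hit <- data.frame(species = "X y", genus = "X",
                    identity_pct = 100 * 620 / 627, # 98.88, renders 98.9
                    marker = "rbcL", stringsAsFactors = FALSE)
  expect_equal(assign_taxonomy(hit)$call_level, "unidentifiable")
  hit$identity_pct <- 100 * 621 / 627 # 99.04
  expect_equal(assign_taxonomy(hit)$call_level, "species")
})

test_that("raising the threshold never rescues a call", {
  set.seed(63)
  rank <- c(unidentifiable = 0, ambiguous_multi_genus = 1, genus = 2,
            species = 3)
  for (rep in 1:20) {
    n <- sample(1:5, 1)
    genera <- sample(c("Aa", "Bb"), n, replace = TRUE)
    hits <- data.frame(
      species = paste(genera, sample(letters, n)),
      genus = genera,
      identity_pct = sort(runif(n, 97, 100), decreasing = TRUE),
      marker = "rbcL", stringsAsFactors = FALSE)
    hits <- hits[order(-hits$identity_pct, hits$species, method = "radix"), ]
    lo <- assign_taxonomy(hits, threshold_pct = 98)
    hi <- assign_taxonomy(hits, threshold_pct = 99.5)
    identified <- function(a) a$call_level != "unidentifiable"
    expect_true(!identified(hi) || identified(lo))
    expect_lte(nrow(hi$qualifying_hits), nrow(lo$qualifying_hits))
  }
})

test_that("marker reconciliation follows specificity then marker precedence", {
  hit <- function(species, id, marker) data.frame(
    species = species, genus = sub("\\s.*", "", species),
    identity_pct = id, marker = marker, stringsAsFactors = FALSE)

  # the Prunella pattern: rbcL ambiguous within the genus, trnH resolves
  r_rbcl <- assign_taxonomy(hit(c("Prunella grandiflora",
                                  "Prunella vulgaris"),
                                c(100, 99.6), "rbcL"))
  r_trnh <- assign_taxonomy(hit("Prunella grandiflora", 100, "trnH-psbA"))
  out <- reconcile_markers(r_rbcl, r_trnh)
  expect_equal(out$call_level, "species")
  expect_equal(out$call_name, "Prunella grandiflora")
  expect_equal(out$source_marker, "trnH-psbA")

  # one-marker detection passes through
  out <- reconcile_markers(r_trnh = assign_taxonomy(
    hit("Teucrium montanum", 100, "trnH-psbA")))
  expect_equal(out$call_name, "Teucrium montanum")

  # both genus-level -> genus
  g1 <- assign_taxonomy(hit(c("Acer campestre", "Acer platanoides"),
                            c(100, 99.8), "rbcL"))
  g2 <- assign_taxonomy(hit(c("Acer campestre", "Acer platanoides"),
                            c(100, 99.6), "trnH-psbA"))
  out <- reconcile_markers(g1, g2)
  expect_equal(out$call_level, "genus")
  expect_equal(out$call_name, "Acer sp.")

  # identical species calls -> that species, no conflict
  s1 <- assign_taxonomy(hit("Fagus sylvatica", 100, "rbcL"))
  s2 <- assign_taxonomy(hit("Fagus sylvatica", 100, "trnH-psbA"))
  out <- reconcile_markers(s1, s2)
  expect_equal(out$call_name, "Fagus sylvatica")
  expect_false(out$conflict)

  # disagreeing species calls are flagged, never silently merged
  s3 <- assign_taxonomy(hit("Rosa canina", 100, "rbcL"))
  expect_warning(out <- reconcile_markers(s3, s2), "disagree")
  expect_true(out$conflict)
  expect_equal(out$source_marker, "trnH-psbA")

  expect_error(reconcile_markers(), "at least one")
})
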