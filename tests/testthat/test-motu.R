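test_that("reads within the error radius of one template form one MOTU", {
  set.seed(51)
  tmpl <- rand_dna(200)
  # substitutions at shared hotspot positions, as in clone libraries where
  # errors recur at the same sites: all reads pairwise within 2 mismatches
  hot <- sample(200, 2)
  reads <- c(tmpl, vapply(1:27, function(i)
    substitute_at(tmpl, positions = sample(hot, sample(1:2, 1))), ""))
  lib <- make_library(reads)
  motus <- cluster_motus(lib)
  expect_equal(length(motus), 1)
  expect_equal(motus[[1]]$n_clones, 28)
})

test_that("distant templates never merge", {
  set.seed(52)
  tmpl_x <- rand_dna(200)
  tmpl_y <- substitute_at(tmpl_x, 60)
  reads <- c(vapply(1:10, function(i) substitute_at(tmpl_x,
                                                    positions = 3), ""),
             vapply(1:10, function(i) substitute_at(tmpl_y,
                                                    positions = 7), ""))
  motus <- cluster_motus(make_library(reads))
  expect_equal(length(motus), 2)
  expect_equal(sort(vapply(motus, `[[`, 0L, "n_clones")), c(10L, 10L))
})

test_that("clustering conserves clone counts and handles edge cases", {
  expect_equal(length(cluster_motus(make_library(character()))), 0)
  set.seed(53)
  reads <- c(replicate(7, rand_dna(80)),
             replicate(3, substitute_at(rand_dna(80), 1)))
  motus <- cluster_motus(make_library(reads))
  expect_equal(sum(vapply(motus, `[[`, 0L, "n_clones")), 10)
  lib_mixed <- make_library(rep(rand_dna(40), 2))
  lib_mixed$site <- c("A", "B")
  expect_error(cluster_motus(lib_mixed), "share one")
})

test_that("max_mismatches = 0 is exact dereplication", {
  set.seed(54)
  useqs <- replicate(6, rand_dna(60))
  reads <- sample(rep(useqs, times = c(4, 3, 2, 1, 1, 1)))
  motus <- cluster_motus(make_library(reads), max_mismatches = 0)
  expect_equal(length(motus), 6)
  expect_equal(vapply(motus, `[[`, 0L, "n_clones"), c(4L, 3L, 2L, 1L, 1L, 1L))
})

test_that("clustering and MOTU order are invariant to input order", {
  set.seed(55)
  tmpl_a <- rand_dna(120)
  tmpl_b <- substitute_at(tmpl_a, 40)
  reads <- c(rep(tmpl_a, 5), vapply(1:4, function(i)
    substitute_at(tmpl_a, 1), ""), rep(tmpl_b, 3))
  lib <- make_library(reads)
  m1 <- cluster_motus(lib)
  shuffled <- lib[sample(nrow(lib)), ]
  m2 <- cluster_motus(shuffled)
  expect_equal(vapply(m1, `[[`, "", "representative"),
               vapply(m2, `[[`, "", "representative"))
  expect_equal(vapply(m1, `[[`, 0L, "n_clones"),
               vapply(m2, `[[`, 0L, "n_clones"))
  expect_equal(vapply(m1, `[[`, "", "consensus"),
               vapply(m2, `[[`, "", "consensus"))
  # representative is the most frequent exact sequence
  expect_equal(m1[[1]]$representative, tmpl_a)
})

test_that("clustering matches the brute-force single-linkage oracle", {
  set.seed(56)
  for (rep in 1:8) {
    n_templates <- sample(2:4, 1)
    templates <- replicate(n_templates, rand_dna(30))
    reads <- unlist(lapply(templates, function(t)
      c(t, replicate(sample(2:5, 1), substitute_at(t, sample(0:3, 1))))))
    reads <- sample(reads)[seq_len(min(20, length(reads)))]
    lib <- make_library(reads)
    got <- partition_of_motus(cluster_motus(lib), lib)
    want <- oracle_single_linkage(reads)
    expect_equal(got, want)
  }
})

test_that("consensus takes the columnwise majority, ties to representative", {
  set.seed(57)
  tmpl <- rand_dna(100)
  # 9 exact copies + 1 read with a single substitution -> template
  lib <- make_library(c(rep(tmpl, 9), substitute_at(tmpl, positions = 50)))
  motus <- cluster_motus(lib)
  expect_equal(length(motus), 1)
  expect_equal(motus[[1]]$consensus, tmpl)
  # three identical reads -> that sequence; singleton -> the member
  lib3 <- make_library(rep(tmpl, 3))
  expect_equal(cluster_motus(lib3)[[1]]$consensus, tmpl)
  lib1 <- make_library(substitute_at(tmpl, 2))
  expect_equal(cluster_motus(lib1)[[1]]$consensus, lib1$sequence[1])
  expect_error(motu_consensus(list(members = data.frame(
    sequence = character()), representative = "A")), "empty")
})

test_that("MOTU tables and FASTA export carry the sample annotation", {
  set.seed(58)
  tmpl <- rand_dna(90)
  lib <- make_library(c(rep(tmpl, 3), substitute_at(tmpl, 30)),
                      site = "Ortanella", date = "II", marker = "trnH-psbA")
  motus <- cluster_motus(lib)
  df <- as.data.frame(motus)
  expect_equal(df$site, rep("Ortanella", 2))
  expect_equal(df$marker, rep("trnH-psbA", 2))
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_motus(motus, fa, tsv)
  expect_equal(nrow(read.delim(tsv)), 2)
})
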