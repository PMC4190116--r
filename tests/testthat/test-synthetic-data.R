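small_cfg <- function(seed = 1, ...) {
  simulation_config(n_species = 16, n_genera = 6, seq_len_rbcl = 150,
                    seq_len_trnh = 160, seed = seed, ...)
}

test_that("reference generation is deterministic and structured by genus", {
  db1 <- generate_reference_set(small_cfg())
  db2 <- generate_reference_set(small_cfg())
  expect_identical(as.data.frame(db1), as.data.frame(db2))
  expect_equal(nrow(db1), 32)
  expect_equal(length(unique(db1$genus)), 6)
  # every genus occupied; both markers per species
  expect_true(all(table(db1$species) == 2))
})

test_that("congener identity sits in the near-threshold band", {
  # two species, one genus, each carrying round(0.004 * 500) = 2
  # substitutions from the shared ancestor: expected pairwise distance 4
  # minus the chance of hitting the same site
  cfg <- simulation_config(n_species = 2, n_genera = 1,
                           seq_len_rbcl = 500, seq_len_trnh = 500,
                           congener_divergence = c(0.004, 0.004), seed = 9)
  ids <- vapply(1:20, function(i) {
    cfg$seed <- i
    db <- generate_reference_set(cfg)
    r <- refs_for_marker(db, "rbcL")
    percent_identity(r$sequence[1], r$sequence[2])
  }, 0)
  expect_true(all(ids >= 99.0 & ids <= 100))
  expect_lt(abs(mean(ids) - (100 * (500 - 4) / 500)), 0.15)
})

test_that("distinct genera are far below the identity threshold", {
  cfg <- simulation_config(n_species = 10, n_genera = 10,
                           seq_len_rbcl = 300, seq_len_trnh = 300, seed = 4)
  db <- generate_reference_set(cfg)
  r <- refs_for_marker(db, "rbcL")
  pairs <- combn(10, 2)[, 1:20]
  ids <- apply(pairs, 2, function(p)
    percent_identity(r$sequence[p[1]], r$sequence[p[2]], band = 25))
  expect_lt(mean(ids), 95)
  expect_true(all(ids < 99))
})

test_that("clone libraries follow the substitution error model exactly", {
  db <- generate_reference_set(small_cfg())
  sp <- unique(db$species)[1:4]
  mix <- mixture_spec("S1", "D1", setNames(rep(0.25, 4), sp),
                      n_clones = 60, subs_per_clone = c(1, 2))
  lib <- generate_clone_library(db, mix, "rbcL", seed = 17)
  expect_equal(nrow(lib), 60)
  templates <- setNames(refs_for_marker(db, "rbcL")$sequence,
                        refs_for_marker(db, "rbcL")$species)
  d <- mapply(function(s, t) hamming(s, templates[[t]]),
              lib$sequence, lib$truth_species)
  expect_true(all(d %in% c(1, 2)))
  # truth-label conservation
  expect_equal(sum(table(lib$truth_species)), 60)
  # determinism
  lib2 <- generate_clone_library(db, mix, "rbcL", seed = 17)
  expect_identical(lib, lib2)
})

test_that("subs_per_clone = [0, 0] reproduces templates verbatim", {
  db <- generate_reference_set(small_cfg())
  sp <- unique(db$species)[1:3]
  mix <- mixture_spec("S1", "D1", setNames(rep(1 / 3, 3), sp),
                      n_clones = 30, subs_per_clone = c(0, 0))
  lib <- generate_clone_library(db, mix, "trnH-psbA", seed = 2)
  templates <- setNames(refs_for_marker(db, "trnH-psbA")$sequence,
                        refs_for_marker(db, "trnH-psbA")$species)
  expect_true(all(lib$sequence == templates[lib$truth_species]))
})

test_that("clone species counts follow the mixture multinomially", {
  cfg <- simulation_config(n_species = 2, n_genera = 2, seq_len_rbcl = 40,
                           seq_len_trnh = 40, seed = 3)
  db <- generate_reference_set(cfg)
  sp <- unique(db$species)
  mix <- mixture_spec("S1", "D1", setNames(c(0.5, 0.5), sp),
                      n_clones = 10000, subs_per_clone = c(0, 0))
  lib <- generate_clone_library(db, mix, "rbcL", seed = 5)
  counts <- table(lib$truth_species)
  sigma <- sqrt(10000 * 0.25)
  expect_lt(abs(counts[[1]] - 5000), 3 * sigma)
})

test_that("contaminants are generated below the identity threshold", {
  db <- generate_reference_set(small_cfg(seed = 8))
  sp <- unique(db$species)[1:4]
  mix <- mixture_spec("S1", "D1", setNames(rep(0.25, 4), sp),
                      n_clones = 100, contaminant_fraction = 0.05)
  lib <- generate_clone_library(db, mix, "rbcL", seed = 19)
  n_cont <- sum(lib$is_contaminant)
  expect_gt(n_cont, 0)            # binomial draw around 5 of 100
  expect_lt(n_cont, 15)
  refs <- refs_for_marker(db, "rbcL")
  for (s in lib$sequence[lib$is_contaminant]) {
    hits <- match_reference(s, db, "rbcL", band = 25)
    expect_lt(max(hits$identity_pct), 99)
  }
  expect_true(all(is.na(lib$truth_species[lib$is_contaminant])))
})

test_that("mixture and config validation reject bad inputs", {
  expect_error(mixture_spec("S", "D", c(a = 0.5, b = 0.4)), "sum to 1")
  expect_error(mixture_spec("S", "D", c(a = 1), subs_per_clone = c(2, 1)),
               "non-decreasing")
  expect_error(simulation_config(n_species = 3, n_genera = 5), "n_genera")
  expect_error(simulation_config(congener_divergence = c(0.01, 0.2)),
               "intergenus")
  db <- generate_reference_set(small_cfg())
  mix <- mixture_spec("S", "D", c("Nonexistent species" = 1))
  expect_error(generate_clone_library(db, mix, "rbcL", 1),
               "Nonexistent species")
})

test_that("study scenarios cover sites x dates x markers deterministically", {
  db <- generate_reference_set(small_cfg(seed = 21))
  sp <- unique(db$species)
  pools <- list(A = sp[1:8], B = sp[5:12], C = sp[9:16])
  libs <- generate_study_scenario(db, pools, dates = c("d1", "d2", "d3"),
                                  n_species_range = c(3, 5), n_clones = 10,
                                  seed = 31)
  expect_equal(length(libs), 18) # 3 sites x 3 dates x 2 markers
  libs2 <- generate_study_scenario(db, pools, dates = c("d1", "d2", "d3"),
                                   n_species_range = c(3, 5), n_clones = 10,
                                   seed = 31)
  expect_identical(libs, libs2)
  # both markers of one (site, date) share the composition
  mixes <- attr(libs, "mixtures")
  expect_equal(length(mixes), 9)
  for (nm in names(mixes)) {
    expect_true(all(names(mixes[[nm]]$composition) %in%
                      pools[[mixes[[nm]]$site]]))
  }
  expect_error(generate_study_scenario(db, list(A = character()),
                                       dates = "d1"), "empty species pool")
})

test_that("clone libraries round-trip through annotated FASTA", {
  db <- generate_reference_set(small_cfg())
  sp <- unique(db$species)[1:3]
  mix <- mixture_spec("Ortanella", "2011-05-20",
                      setNames(rep(1 / 3, 3), sp), n_clones = 20,
                      contaminant_fraction = 0.1)
  lib <- generate_clone_library(db, mix, "rbcL", seed = 4)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_clone_library(lib, fa)
  back <- read_clone_library(fa)
  expect_equal(as.data.frame(back), as.data.frame(lib))
})
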