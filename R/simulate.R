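#' Configuration for the reference-database simulator
#'
#' The simulator emulates a local two-marker flora database: for each genus
#' an ancestor sequence per marker is drawn uniformly over \{A, C, G, T\},
#' and each species derives from its genus ancestor by a number of random
#' substitutions set by its drawn per-site divergence. Congeners are
#' therefore nearly identical (default divergence 0.2-1\% per species, i.e.
#' pairwise congener identities in the ~98-99.6\% band), while distinct
#' genera are unrelated random sequences, far below any identity threshold.
#'
#' @param n_species Number of species in the database.
#' @param n_genera Number of genera (must not exceed `n_species`).
#' @param seq_len_rbcl,seq_len_trnh Marker sequence lengths in nt.
#' @param congener_divergence Range (length 2) of per-species substitutions
#'   per site from the genus ancestor.
#' @param intergenus_divergence Range of minimum between-genus divergence;
#'   drawing ancestors independently at random always exceeds it, and the
#'   configuration requires `max(congener) < min(intergenus)`.
#' @param status_probs Named probabilities for the status labels
#'   common/rare/alien.
#' @param seed Integer seed; the generated database is a deterministic
#'   function of the configuration.
#' @return Object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_species = 693L,
                              n_genera = 250L,
                              seq_len_rbcl = 627L,
                              seq_len_trnh = 634L,
                              congener_divergence = c(0.002, 0.01),
                              intergenus_divergence = c(0.05, 0.20),
                              status_probs = c(common = 0.80, rare = 0.15,
                                               alien = 0.05),
                              seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              n_genera = as.integer(n_genera),
              seq_len_rbcl = as.integer(seq_len_rbcl),
              seq_len_trnh = as.integer(seq_len_trnh),
              congener_divergence = as.numeric(congener_divergence),
              intergenus_divergence = as.numeric(intergenus_divergence),
              status_probs = status_probs,
              seed = as.integer(seed))
  if (cfg$n_species < 1L) stop("n_species must be >= 1", call. = FALSE)
  if (cfg$n_species < cfg$n_genera) {
    stop("n_species must be >= n_genera", call. = FALSE)
  }
  if (length(cfg$congener_divergence) != 2L ||
      length(cfg$intergenus_divergence) != 2L) {
    stop("divergence settings must be ranges of length 2", call. = FALSE)
  }
  if (!(cfg$congener_divergence[2L] > 0 &&
        cfg$congener_divergence[2L] < cfg$intergenus_divergence[1L])) {
    stop("require 0 < max(congener_divergence) < min(intergenus_divergence)",
         call. = FALSE)
  }
  if (!identical(sort(names(cfg$status_probs)), sort(STATUS_LEVELS)) ||
      abs(sum(cfg$status_probs) - 1) > 1e-8) {
    stop("status_probs must be named common/rare/alien and sum to 1",
         call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

#' @noRd
random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Introduce k random substitutions into a sequence
#'
#' Positions are drawn without replacement and the substituted base always
#' differs from the original, so the Hamming distance to the input is
#' exactly `k`.
#'
#' @param sequence A DNA string over \{A, C, G, T\}.
#' @param k Number of substitutions (0 returns the input unchanged).
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(sequence, k) {
  k <- as.integer(k)
  if (k == 0L) return(sequence)
  chars <- strsplit(sequence, "")[[1L]]
  if (k > length(chars)) stop("k exceeds sequence length", call. = FALSE)
  pos <- sample.int(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic two-marker reference database
#'
#' @param cfg A [simulation_config()].
#' @return A [reference_db()] with `2 * n_species` records (one per marker
#'   per species), deterministic under `cfg$seed`.
#' @export
generate_reference_set <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  withr::with_seed(cfg$seed, {
    # species-to-genus map: every genus gets at least one species
    genus_of <- c(seq_len(cfg$n_genera),
                  if (cfg$n_species > cfg$n_genera) {
                    sample.int(cfg$n_genera, cfg$n_species - cfg$n_genera,
                               replace = TRUE)
                  })
    genus_names <- sprintf("Genus%03d", seq_len(cfg$n_genera))
    species_names <- sprintf("%s species%03d", genus_names[genus_of],
                             seq_len(cfg$n_species))
    status <- sample(names(cfg$status_probs), cfg$n_species, replace = TRUE,
                     prob = cfg$status_probs)

    lens <- c(rbcL = cfg$seq_len_rbcl, `trnH-psbA` = cfg$seq_len_trnh)
    recs <- lapply(MARKERS, function(marker) {
      ancestors <- vapply(seq_len(cfg$n_genera),
                          function(i) random_dna(lens[[marker]]), "")
      seqs <- vapply(seq_len(cfg$n_species), function(i) {
        d <- stats::runif(1L, cfg$congener_divergence[1L],
                          cfg$congener_divergence[2L])
        mutate_sequence(ancestors[genus_of[i]],
                        round(d * lens[[marker]]))
      }, "")
      data.frame(record_id = sprintf("SP%04d_%s", seq_len(cfg$n_species),
                                     sub("-psbA", "", marker)),
                 species = species_names, marker = marker,
                 status = status, sequence = seqs,
                 stringsAsFactors = FALSE)
    })
    recs <- do.call(rbind, recs)
    reference_db(record_id = recs$record_id, species = recs$species,
                 marker = recs$marker, sequence = recs$sequence,
                 status = recs$status, accession = "")
  })
}

#' Specification of one simulated pollen mixture
#'
#' @param site,date Sample labels.
#' @param composition Named numeric vector of relative abundances
#'   (species -> proportion), strictly positive and summing to 1.
#' @param n_clones Number of clones sequenced from the mixture.
#' @param subs_per_clone Integer range of substitutions per clone (each
#'   clone receives an exact, uniformly drawn count from this range).
#' @param contaminant_fraction Per-clone probability of being an
#'   off-database contaminant.
#' @return Object of class `mixture_spec`.
#' @export
mixture_spec <- function(site, date, composition, n_clones = 100L,
                         subs_per_clone = c(1L, 2L),
                         contaminant_fraction = 0) {
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    stop("`composition` must be a named vector (species -> abundance)",
         call. = FALSE)
  }
  if (any(composition <= 0) || abs(sum(composition) - 1) > 1e-6) {
    stop("abundances must be > 0 and sum to 1", call. = FALSE)
  }
  n_clones <- as.integer(n_clones)
  subs_per_clone <- as.integer(subs_per_clone)
  if (n_clones < 1L) stop("n_clones must be >= 1", call. = FALSE)
  if (length(subs_per_clone) != 2L || subs_per_clone[1L] < 0L ||
      subs_per_clone[1L] > subs_per_clone[2L]) {
    stop("subs_per_clone must be a non-decreasing range with min >= 0",
         call. = FALSE)
  }
  if (contaminant_fraction < 0 || contaminant_fraction > 1) {
    stop("contaminant_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(list(site = site, date = date, composition = composition,
                 n_clones = n_clones, subs_per_clone = subs_per_clone,
                 contaminant_fraction = contaminant_fraction),
            class = "mixture_spec")
}

#' Simulate a clone library from a pollen mixture
#'
#' Each clone's species is drawn from the mixture composition
#' (multinomially); the clone sequence is the species' reference template
#' with an exact number of random substitutions drawn uniformly from
#' `subs_per_clone`. Contaminant clones (drawn per clone with probability
#' `contaminant_fraction`) are uniform random sequences regenerated until
#' their identity to every reference of the marker is below 99\%; their
#' `truth_species` is `NA`. Truth labels are retained for evaluation.
#'
#' @param db A [reference_db()] containing every mixture species for
#'   `marker`.
#' @param mix A [mixture_spec()].
#' @param marker `"rbcL"` or `"trnH-psbA"`.
#' @param seed Integer seed for this library.
#' @param scoring,band Alignment settings used for the contaminant
#'   rejection check (see [global_align()]).
#' @return Object of class `clone_library`: a data frame with columns
#'   `read_id`, `site`, `date`, `marker`, `sequence`, `truth_species`,
#'   `is_contaminant`.
#' @export
generate_clone_library <- function(db, mix, marker, seed,
                                   scoring = default_scoring(), band = 25L) {
  stopifnot(inherits(mix, "mixture_spec"))
  check_marker(marker)
  refs <- refs_for_marker(db, marker)
  sp <- names(mix$composition)
  missing <- setdiff(sp, refs$species)
  if (length(missing) > 0) {
    stop("species not in reference database for ", marker, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  templates <- setNames(refs$sequence[match(sp, refs$species)], sp)
  contaminant_len <- max(nchar(refs$sequence))

  withr::with_seed(seed, {
    n <- mix$n_clones
    is_cont <- rbinom(n, 1L, mix$contaminant_fraction) == 1L
    truth <- rep(NA_character_, n)
    n_real <- sum(!is_cont)
    if (n_real > 0) {
      truth[!is_cont] <- sample(sp, n_real, replace = TRUE,
                                prob = mix$composition)
    }
    seqs <- character(n)
    for (i in seq_len(n)) {
      if (is_cont[i]) {
        repeat {
          cand <- random_dna(contaminant_len)
          ids <- identity_to_refs(cand, refs$sequence, scoring, band)
          if (max(ids) < 99) break
        }
        seqs[i] <- cand
      } else {
        k <- sample(seq(mix$subs_per_clone[1L], mix$subs_per_clone[2L]), 1L)
        seqs[i] <- mutate_sequence(templates[[truth[i]]], k)
      }
    }
    structure(data.frame(
      read_id = sprintf("clone%03d", seq_len(n)),
      site = mix$site, date = mix$date, marker = marker,
      sequence = seqs, truth_species = truth, is_contaminant = is_cont,
      stringsAsFactors = FALSE
    ), class = c("clone_library", "data.frame"))
  })
}

#' Simulate a full multi-site, multi-date, two-marker study
#'
#' For each (site, date) one mixture of `n_species_range` species is drawn
#' from that site's species pool with Dirichlet(1) relative abundances, and
#' both markers are cloned from that shared composition (both markers are
#' amplified from the same pooled DNA).
#'
#' @param db A [reference_db()].
#' @param site_floras Named list: site -> character vector of species
#'   available at that site (must be present in `db` for both markers).
#' @param dates Character vector of sampling dates, in temporal order.
#' @param n_species_range Integer range of per-sample mixture richness.
#' @param n_clones,subs_per_clone,contaminant_fraction Passed to
#'   [mixture_spec()].
#' @param seed Master seed; per-library seeds are derived from it.
#' @param scoring,band Alignment settings for contaminant rejection.
#' @return Named list of [generate_clone_library()] results, one per
#'   (site, date, marker), names `"site|date|marker"`, plus attribute
#'   `mixtures` (the shared per-(site, date) mixture specs).
#' @export
generate_study_scenario <- function(db, site_floras, dates,
                                    n_species_range = c(12L, 18L),
                                    n_clones = 100L,
                                    subs_per_clone = c(1L, 2L),
                                    contaminant_fraction = 0,
                                    seed = 1L,
                                    scoring = default_scoring(),
                                    band = 25L) {
  if (length(site_floras) == 0 || is.null(names(site_floras))) {
    stop("`site_floras` must be a named list of species pools",
         call. = FALSE)
  }
  for (s in names(site_floras)) {
    if (length(site_floras[[s]]) == 0) {
      stop("empty species pool for site ", s, call. = FALSE)
    }
  }
  cells <- expand.grid(date = dates, site = names(site_floras),
                       stringsAsFactors = FALSE)[, c("site", "date")]
  withr::with_seed(seed, {
    lib_seeds <- sample.int(.Machine$integer.max, 2L * nrow(cells))
    mixtures <- list()
    for (r in seq_len(nrow(cells))) {
      pool <- site_floras[[cells$site[r]]]
      s <- sample(seq(n_species_range[1L], n_species_range[2L]), 1L)
      s <- min(s, length(pool))
      species <- sample(pool, s)
      ab <- stats::rexp(s)
      mixtures[[r]] <- mixture_spec(
        site = cells$site[r], date = cells$date[r],
        composition = setNames(ab / sum(ab), species),
        n_clones = n_clones, subs_per_clone = subs_per_clone,
        contaminant_fraction = contaminant_fraction)
    }
  })
  libs <- list()
  k <- 0L
  for (r in seq_len(nrow(cells))) {
    for (marker in MARKERS) {
      k <- k + 1L
      nm <- paste(cells$site[r], cells$date[r], marker, sep = "|")
      libs[[nm]] <- generate_clone_library(db, mixtures[[r]], marker,
                                           seed = lib_seeds[k],
                                           scoring = scoring, band = band)
    }
  }
  names(mixtures) <- paste(cells$site, cells$date, sep = "|")
  attr(libs, "mixtures") <- mixtures
  libs
}

#' Write a clone library as FASTA
#'
#' Headers carry the sample annotation as
#' `read_id|site|date|marker|truth_species` (empty truth field for
#' contaminants).
#'
#' @param lib A `clone_library`.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_clone_library <- function(lib, path) {
  headers <- paste(lib$read_id, lib$site, lib$date, lib$marker,
                   ifelse(is.na(lib$truth_species), "", lib$truth_species),
                   sep = "|")
  seqs <- Biostrings::DNAStringSet(setNames(lib$sequence, headers))
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read a clone library written by [write_clone_library()]
#'
#' @param path FASTA path.
#' @return A `clone_library` data frame.
#' @export
read_clone_library <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(parts) < 4L)) {
    stop("clone FASTA headers must be read_id|site|date|marker|truth_species",
         call. = FALSE)
  }
  field <- function(i) vapply(parts, function(p) {
    if (length(p) >= i) p[i] else ""
  }, "")
  truth <- field(5L)
  structure(data.frame(
    read_id = field(1L), site = field(2L), date = field(3L),
    marker = field(4L),
    sequence = unname(normalize_dna(as.character(seqs))),
    truth_species = ifelse(nzchar(truth), truth, NA_character_),
    is_contaminant = !nzchar(truth),
    stringsAsFactors = FALSE
  ), class = c("clone_library", "data.frame"))
}
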