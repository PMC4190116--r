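#' Pipeline configuration
#'
#' Collects the tunable parameters of the identification pipeline. Defaults
#' are the study conditions: a 99\% identity threshold, a 2-mismatch MOTU
#' radius matching the 1-2 substitutions-per-clone error model,
#' \emph{trnH-psbA} precedence at equal call specificity, and 1,000
#' accumulation-curve iterations. `band` is the diagonal band half-width
#' used for the pipeline's high-volume alignments (see [global_align()]).
#'
#' @param threshold_pct Identity threshold in percent (0 < t <= 100).
#' @param motu_max_mismatches MOTU linkage radius in mismatch columns.
#' @param scoring Alignment scoring scheme (see [default_scoring()]).
#' @param marker_precedence Marker that wins reconciliation ties.
#' @param n_iterations Accumulation-curve iterations.
#' @param band Diagonal band half-width for pipeline alignments.
#' @param include_unidentified Count unidentifiable MOTUs as pseudo-taxa in
#'   accumulation curves.
#' @param seed Base seed for the pipeline's randomized steps.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold_pct = 99.0,
                            motu_max_mismatches = 2L,
                            scoring = default_scoring(),
                            marker_precedence = "trnH-psbA",
                            n_iterations = 1000L,
                            band = 25L,
                            include_unidentified = TRUE,
                            seed = 1L) {
  if (!(threshold_pct > 0 && threshold_pct <= 100)) {
    stop("threshold_pct must be in (0, 100]", call. = FALSE)
  }
  check_marker(marker_precedence)
  check_scoring(scoring)
  structure(list(threshold_pct = threshold_pct,
                 motu_max_mismatches = as.integer(motu_max_mismatches),
                 scoring = scoring,
                 marker_precedence = marker_precedence,
                 n_iterations = as.integer(n_iterations),
                 band = band,
                 include_unidentified = isTRUE(include_unidentified),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML (or JSON)
#'
#' Fields present in the file override the defaults of
#' [pipeline_config()]; everything else keeps its default.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) config file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Identify the MOTUs of one clone library
#'
#' Runs the per-sample stages: single-linkage MOTU clustering, consensus
#' building, reference matching, and threshold-based taxonomic assignment.
#'
#' @param lib A `clone_library` (one site, date and marker).
#' @param db A [reference_db()].
#' @param config A [pipeline_config()].
#' @return A `sample_report` data frame with one row per MOTU: `site`,
#'   `date`, `marker`, `motu_id`, `n_clones`, `call_level`, `call_name`,
#'   `best_identity_pct`, `n_qualifying`, `hits` (qualifying hits listed
#'   exhaustively, else the top 3, rendered to one decimal),
#'   `external_lookup`, and for simulated reads the majority
#'   `truth_species` and `n_contaminant` members. Attributes `motus` and
#'   `assignments` carry the full objects.
#' @export
assign_clone_library <- function(lib, db, config = pipeline_config()) {
  if (nrow(lib) == 0) {
    warning("empty clone library: empty report", call. = FALSE)
    out <- data.frame(site = character(), date = character(),
                      marker = character(), motu_id = character(),
                      n_clones = integer(), call_level = character(),
                      call_name = character(),
                      best_identity_pct = numeric(),
                      n_qualifying = integer(), hits = character(),
                      external_lookup = logical(),
                      stringsAsFactors = FALSE)
    class(out) <- c("sample_report", "data.frame")
    return(out)
  }
  motus <- cluster_motus(lib, max_mismatches = config$motu_max_mismatches,
                         scoring = config$scoring, band = config$band)
  marker <- attr(motus, "marker")
  assignments <- lapply(motus, function(m) {
    hits <- match_reference(m$consensus, db, marker,
                            scoring = config$scoring, band = config$band)
    assign_taxonomy(hits, threshold_pct = config$threshold_pct,
                    motu_id = m$motu_id, marker = marker)
  })
  rows <- lapply(seq_along(motus), function(i) {
    m <- motus[[i]]
    a <- assignments[[i]]
    shown <- if (nrow(a$qualifying_hits) > 0) a$qualifying_hits else
      head(a$hits, 3L)
    data.frame(
      site = attr(motus, "site"), date = attr(motus, "date"),
      marker = marker, motu_id = m$motu_id, n_clones = m$n_clones,
      call_level = a$call_level, call_name = a$call_name,
      best_identity_pct = if (nrow(a$hits) > 0) a$hits$identity_pct[1L]
        else NA_real_,
      n_qualifying = nrow(a$qualifying_hits),
      hits = paste(sprintf("%s (%.1f)", shown$species, shown$identity_pct),
                   collapse = "; "),
      external_lookup = flag_for_external_lookup(a),
      truth_species = if ("truth_species" %in% names(m$members)) {
        tt <- table(m$members$truth_species, useNA = "no")
        if (length(tt) > 0) names(tt)[which.max(tt)] else NA_character_
      } else NA_character_,
      n_contaminant = if ("is_contaminant" %in% names(m$members)) {
        sum(m$members$is_contaminant)
      } else NA_integer_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sample_report", "data.frame")
  attr(out, "motus") <- motus
  attr(out, "assignments") <- assignments
  out
}

#' Identify every clone library of a study scenario
#'
#' @param libs Named list of `clone_library` objects (e.g. from
#'   [generate_study_scenario()]).
#' @param db A [reference_db()].
#' @param config A [pipeline_config()].
#' @return Named list of `sample_report` data frames.
#' @export
analyze_scenario <- function(libs, db, config = pipeline_config()) {
  lapply(libs, assign_clone_library, db = db, config = config)
}

#' @noRd
sampling_labels_for <- function(dates) {
  romans <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X")
  u <- sort(unique(dates))
  if (length(u) > length(romans)) stop("too many sampling dates",
                                       call. = FALSE)
  setNames(romans[seq_along(u)], u)
}

#' Reconcile markers and summarize reports into a community table
#'
#' Pools the per-marker sample reports of a study into a long composition
#' table and a presence/absence matrix. Within each (site, sampling) cell,
#' cross-marker reconciliation is keyed by genus, following the
#' specificity-precedence of [reconcile_markers()]: a genus-level call
#' ("Genus sp.") is absorbed by a species-level call of the same genus in
#' the same cell (and its clones counted under that species when the
#' species is unique); genus-level calls never resolved by the other
#' marker stay "Genus sp."; ambiguous and unidentifiable MOTUs are
#' excluded from the matrix.
#'
#' @param reports List of `sample_report` data frames covering the study.
#' @param sampling_labels Optional named vector date -> sampling label;
#'   defaults to I, II, III over the sorted unique dates.
#' @param metadata Optional per-taxon metadata for the matrix (see
#'   [build_presence_absence()]).
#' @return List with `composition` (long data frame: `taxon`, `site`,
#'   `sampling`, `marker`, `n_clones`, `call_level`) and `matrix` (a
#'   [pa_matrix()]).
#' @export
summarize_reports <- function(reports, sampling_labels = NULL,
                              metadata = NULL) {
  if (is.data.frame(reports)) reports <- list(reports)
  rep_df <- do.call(rbind, lapply(reports, as.data.frame))
  if (is.null(rep_df) || nrow(rep_df) == 0) {
    stop("no report rows to summarize", call. = FALSE)
  }
  if (is.null(sampling_labels)) {
    sampling_labels <- sampling_labels_for(rep_df$date)
  }
  rep_df$sampling <- unname(sampling_labels[rep_df$date])

  cells <- unique(rep_df[c("site", "sampling")])
  comp_rows <- list()
  for (r in seq_len(nrow(cells))) {
    cell <- rep_df[rep_df$site == cells$site[r] &
                     rep_df$sampling == cells$sampling[r], , drop = FALSE]
    sp_rows <- cell[cell$call_level == "species", , drop = FALSE]
    sp_by_genus <- split(unique(sp_rows$call_name),
                         sub("\\s.*", "", unique(sp_rows$call_name)))
    taxon <- character(nrow(cell))
    level <- cell$call_level
    for (i in seq_len(nrow(cell))) {
      if (cell$call_level[i] == "species") {
        taxon[i] <- cell$call_name[i]
      } else if (cell$call_level[i] == "genus") {
        genus <- sub("\\s.*", "", cell$call_name[i])
        resolved <- sp_by_genus[[genus]]
        if (length(resolved) == 1L) {
          taxon[i] <- resolved      # absorbed by the other marker's species
          level[i] <- "species"
        } else {
          taxon[i] <- cell$call_name[i]
        }
      } else {
        taxon[i] <- cell$call_name[i]
      }
    }
    comp_rows[[r]] <- data.frame(
      taxon = taxon, site = cell$site, sampling = cell$sampling,
      marker = cell$marker, n_clones = cell$n_clones,
      call_level = level, stringsAsFactors = FALSE)
  }
  comp <- do.call(rbind, comp_rows)
  comp <- stats::aggregate(n_clones ~ taxon + site + sampling + marker +
                             call_level, data = comp, FUN = sum)
  comp <- comp[order(comp$site, comp$sampling, comp$marker, comp$taxon), ,
               drop = FALSE]
  rownames(comp) <- NULL
  m <- build_presence_absence(comp, metadata = metadata,
                              samplings = unique(unname(sampling_labels)))
  list(composition = comp, matrix = m)
}

#' Accumulation curves for every site and marker of a study
#'
#' Pools each site's clones across sampling dates per marker and computes
#' the randomized accumulation curve.
#'
#' @param reports List of `sample_report` data frames.
#' @param config A [pipeline_config()] (uses `n_iterations`,
#'   `include_unidentified` and `seed`).
#' @return Named list of `accumulation_curve` objects, names
#'   `"site|marker"`.
#' @export
rarefy_reports <- function(reports, config = pipeline_config()) {
  if (is.data.frame(reports)) reports <- list(reports)
  rep_df <- do.call(rbind, lapply(reports, as.data.frame))
  sites <- unique(rep_df$site)
  markers <- unique(rep_df$marker)
  curves <- list()
  k <- 0L
  for (s in sites) {
    for (mk in markers) {
      k <- k + 1L
      labels <- pool_site_labels(reports, s, mk,
                                 include_unidentified =
                                   config$include_unidentified)
      if (length(labels) == 0) next
      curves[[paste(s, mk, sep = "|")]] <-
        accumulation_permutation(labels, n_iter = config$n_iterations,
                                 seed = config$seed + k)
    }
  }
  curves
}
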