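#' Presence/absence community matrix
#'
#' Rows are taxa (keyed by the printed taxon name, including "Genus sp."
#' composites), columns are (site, sampling) cells. Per-taxon metadata
#' (status, pollination mode, flowering period) is carried alongside.
#'
#' @param presence Logical matrix, taxa in rows, columns named
#'   `"site|sampling"`.
#' @param taxa Data frame with columns `taxon`, `status`, `pollination`,
#'   `flowering_period`, one row per matrix row.
#' @param sites,samplings Character vectors of site and sampling labels.
#' @return Object of class `pa_matrix`.
#' @export
pa_matrix <- function(presence, taxa, sites, samplings) {
  stopifnot(is.matrix(presence), is.logical(presence),
            nrow(presence) == nrow(taxa))
  if (nrow(presence) > 0 && any(rowSums(presence) == 0)) {
    stop("every taxon must be present in at least one cell", call. = FALSE)
  }
  structure(list(presence = presence, taxa = taxa, sites = sites,
                 samplings = samplings),
            class = "pa_matrix")
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat(sprintf("pa_matrix: %d taxa x %d cells (%d sites x %d samplings)\n",
              nrow(x$presence), ncol(x$presence), length(x$sites),
              length(x$samplings)))
  invisible(x)
}

#' @noRd
site_cols <- function(m, site) {
  if (!site %in% m$sites) stop("unknown site: ", site, call. = FALSE)
  which(startsWith(colnames(m$presence), paste0(site, "|")))
}

#' Build the presence/absence matrix from composition tables
#'
#' A taxon is present in a (site, sampling) cell iff it was detected there
#' by either marker; rows whose `call_level` is `unidentifiable` or
#' `ambiguous_multi_genus` are excluded. Taxon names are expected to be
#' reconciled across markers beforehand (see [summarize_reports()]).
#'
#' @param composition Data frame with columns `taxon`, `site`, `sampling`,
#'   `marker`, `n_clones` and optionally `call_level`.
#' @param metadata Optional data frame with columns `taxon`, `status`,
#'   `pollination`, `flowering_period`; conflicting metadata rows for one
#'   taxon raise an error.
#' @param samplings Sampling labels in order (default I, II, III).
#' @return A [pa_matrix()].
#' @export
build_presence_absence <- function(composition, metadata = NULL,
                                   samplings = c("I", "II", "III")) {
  comp <- as.data.frame(composition)
  if ("call_level" %in% names(comp)) {
    comp <- comp[!comp$call_level %in%
                   c("unidentifiable", "ambiguous_multi_genus"), ,
                 drop = FALSE]
  }
  sites <- unique(comp$site)
  taxa_names <- sort(unique(comp$taxon))
  cells <- as.vector(t(outer(sites, samplings, paste, sep = "|")))
  presence <- matrix(FALSE, nrow = length(taxa_names),
                     ncol = length(cells),
                     dimnames = list(taxa_names, cells))
  if (nrow(comp) > 0) {
    presence[cbind(match(comp$taxon, taxa_names),
                   match(paste(comp$site, comp$sampling, sep = "|"),
                         cells))] <- TRUE
  }
  if (is.null(metadata)) {
    n_tax <- length(taxa_names)
    taxa <- data.frame(taxon = taxa_names,
                       status = rep(NA_character_, n_tax),
                       pollination = rep(NA_character_, n_tax),
                       flowering_period = rep(NA_character_, n_tax),
                       stringsAsFactors = FALSE)
  } else {
    md <- unique(as.data.frame(metadata)[c("taxon", "status", "pollination",
                                           "flowering_period")])
    if (anyDuplicated(md$taxon)) {
      stop("conflicting metadata for taxon: ",
           md$taxon[duplicated(md$taxon)][1L], call. = FALSE)
    }
    taxa <- md[match(taxa_names, md$taxon), , drop = FALSE]
    taxa$taxon <- taxa_names
    rownames(taxa) <- NULL
  }
  pa_matrix(presence, taxa, sites, samplings)
}

#' Load the packaged site-by-sampling presence/absence table
#'
#' The package ships a transcription of the study's presence/absence table
#' of the 52 identified taxa across 3 sites and 3 samplings, with per-taxon
#' flowering period, pollination mode and status; this is the pinned
#' reference community used by the summary statistics tests.
#'
#' @return A [pa_matrix()].
#' @export
pollen_survey_fixture <- function() {
  path <- system.file("extdata", "pollen_survey_presence_absence.tsv",
                      package = "pollenID", mustWork = TRUE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  meta_cols <- c("species", "flowering_period", "pollination", "status")
  cell_cols <- setdiff(names(df), meta_cols)
  cells <- as.matrix(df[cell_cols])
  presence <- !is.na(cells) & cells == "+"
  rownames(presence) <- df$species
  sites <- unique(vapply(strsplit(cell_cols, "|", fixed = TRUE), `[`, "",
                         1L))
  samplings <- unique(vapply(strsplit(cell_cols, "|", fixed = TRUE), `[`,
                             "", 2L))
  taxa <- data.frame(taxon = df$species, status = df$status,
                     pollination = df$pollination,
                     flowering_period = df$flowering_period,
                     stringsAsFactors = FALSE)
  pa_matrix(presence, taxa, sites, samplings)
}

#' Taxon richness per site
#'
#' @param m A [pa_matrix()].
#' @return Named integer vector: number of taxa present in at least one
#'   sampling at each site.
#' @export
richness_per_site <- function(m) {
  vapply(setNames(m$sites, m$sites), function(s) {
    sum(rowSums(m$presence[, site_cols(m, s), drop = FALSE]) > 0)
  }, 0L)
}

#' Number of taxa shared between two sites
#'
#' @param m A [pa_matrix()].
#' @param site_a,site_b Site labels.
#' @return Count of taxa present at both sites.
#' @export
shared_taxa <- function(m, site_a, site_b) {
  a <- rowSums(m$presence[, site_cols(m, site_a), drop = FALSE]) > 0
  b <- rowSums(m$presence[, site_cols(m, site_b), drop = FALSE]) > 0
  sum(a & b)
}

#' Persistence classes of a site's taxa
#'
#' Partitions the taxa detected at a site by the number of samplings in
#' which they were detected.
#'
#' @param m A [pa_matrix()] with three samplings.
#' @param site Site label.
#' @return Named integer vector `c("1" = ..., "2" = ..., "3" = ...)`.
#' @export
persistence_classes <- function(m, site) {
  counts <- rowSums(m$presence[, site_cols(m, site), drop = FALSE])
  n_samp <- length(m$samplings)
  vapply(setNames(seq_len(n_samp), seq_len(n_samp)),
         function(k) sum(counts == k), 0L)
}

#' Taxon counts by status
#'
#' @param m A [pa_matrix()].
#' @return Named integer vector over common/rare/alien.
#' @export
status_counts <- function(m) {
  vapply(setNames(STATUS_LEVELS, STATUS_LEVELS),
         function(s) sum(m$taxa$status == s, na.rm = TRUE), 0L)
}

#' Total number of distinct taxa
#'
#' @param m A [pa_matrix()].
#' @return Integer count.
#' @export
total_taxa <- function(m) {
  nrow(m$presence)
}

#' Number of distinct genera
#'
#' The genus is the first whitespace-delimited token of the taxon name;
#' "Genus sp." composites collapse to their genus.
#'
#' @param m A [pa_matrix()].
#' @return Integer count.
#' @export
genus_count <- function(m) {
  if (nrow(m$presence) == 0) return(0L)
  length(unique(vapply(strsplit(m$taxa$taxon, "\\s+"), `[`, "", 1L)))
}

#' Community summary statistics
#'
#' Convenience wrapper computing all summary statistics of a
#' presence/absence matrix at once.
#'
#' @param m A [pa_matrix()].
#' @return List with `total_taxa`, `genus_count`, `richness`,
#'   `shared` (matrix of pairwise shared-taxon counts), `persistence`
#'   (per site) and `status_counts`.
#' @export
community_summary <- function(m) {
  shared <- outer(m$sites, m$sites,
                  Vectorize(function(a, b) shared_taxa(m, a, b)))
  dimnames(shared) <- list(m$sites, m$sites)
  list(total_taxa = total_taxa(m),
       genus_count = genus_count(m),
       richness = richness_per_site(m),
       shared = shared,
       persistence = lapply(setNames(m$sites, m$sites), function(s)
         persistence_classes(m, s)),
       status_counts = status_counts(m))
}
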