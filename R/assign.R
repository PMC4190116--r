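#' Match a query sequence against the reference database
#'
#' Computes the percent identity of the query to every reference record of
#' the requested marker (one hit per species) and returns the hits sorted
#' by identity descending, species ascending — the machine analog of a
#' BLAST best-hit list against a curated local database.
#'
#' @param query A DNA sequence (typically a MOTU consensus).
#' @param db A [reference_db()].
#' @param marker `"rbcL"` or `"trnH-psbA"`.
#' @param scoring,band Alignment settings (see [global_align()]).
#' @return Data frame of hits with columns `species`, `genus`,
#'   `identity_pct`, `marker`.
#' @export
match_reference <- function(query, db, marker,
                            scoring = default_scoring(), band = NULL) {
  check_marker(marker)
  check_dna(query, "query")
  refs <- refs_for_marker(db, marker)
  if (nrow(refs) == 0) {
    stop("reference database has no records for marker ", marker,
         call. = FALSE)
  }
  ids <- identity_to_refs(query, refs$sequence, check_scoring(scoring), band)
  hits <- data.frame(species = refs$species, genus = refs$genus,
                     identity_pct = ids, marker = marker,
                     stringsAsFactors = FALSE)
  hits <- hits[order(-hits$identity_pct, hits$species, method = "radix"), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' @noRd
check_hits_sorted <- function(hits) {
  need <- c("species", "genus", "identity_pct", "marker")
  if (!is.data.frame(hits) || !all(need %in% names(hits))) {
    stop("`hits` must be a data frame as returned by match_reference()",
         call. = FALSE)
  }
  if (nrow(hits) > 1) {
    ord <- order(-hits$identity_pct, hits$species, method = "radix")
    if (!identical(ord, seq_len(nrow(hits)))) {
      stop("`hits` must be sorted by identity descending, species ascending",
           call. = FALSE)
    }
  }
  hits
}

#' Taxonomic call from a ranked hit list
#'
#' Applies the identity-threshold rule: hits with identity at or above
#' `threshold_pct` (comparison on the unrounded identity) qualify. No
#' qualifying hit makes the MOTU `unidentifiable`; a single qualifying
#' species gives a species-level call; several qualifying congeners give a
#' genus-level call ("Genus sp."); qualifying hits in more than one genus
#' give `ambiguous_multi_genus` with the full hit list retained. A species
#' call therefore requires uniqueness among \emph{all} qualifying hits,
#' not merely the top hit, which is what demotes a 100\% hit with a
#' congener at 99.6\% to the genus level.
#'
#' @param hits Hit list as produced by [match_reference()] (an error is
#'   raised if it is not in that sort order).
#' @param threshold_pct Identity threshold in percent (default 99).
#' @param motu_id,marker Optional annotation carried into the result.
#' @return Object of class `assignment`: list with `motu_id`, `marker`,
#'   `hits`, `qualifying_hits`, `call_level` (one of `species`, `genus`,
#'   `ambiguous_multi_genus`, `unidentifiable`) and `call_name`.
#' @export
assign_taxonomy <- function(hits, threshold_pct = 99.0, motu_id = NA,
                            marker = NULL) {
  check_hits_sorted(hits)
  if (is.null(marker)) {
    marker <- if (nrow(hits) > 0) hits$marker[1L] else NA_character_
  }
  qual <- hits[hits$identity_pct >= threshold_pct, , drop = FALSE]
  if (nrow(qual) == 0) {
    level <- "unidentifiable"
    name <- "unidentifiable"
  } else if (length(unique(qual$species)) == 1L) {
    level <- "species"
    name <- qual$species[1L]
  } else if (length(unique(qual$genus)) == 1L) {
    level <- "genus"
    name <- paste(qual$genus[1L], "sp.")
  } else {
    level <- "ambiguous_multi_genus"
    name <- "ambiguous"
  }
  structure(list(motu_id = motu_id, marker = marker, hits = hits,
                 qualifying_hits = qual, call_level = level,
                 call_name = name),
            class = "assignment")
}

#' @export
print.assignment <- function(x, ...) {
  cat(sprintf("assignment [%s, %s]: %s (%s)\n", x$motu_id, x$marker,
              x$call_name, x$call_level))
  if (nrow(x$qualifying_hits) > 0) {
    h <- x$qualifying_hits
    cat("  qualifying:",
        paste(sprintf("%s (%.1f)", h$species, h$identity_pct),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' @noRd
call_rank <- function(level) {
  c(unidentifiable = 0L, ambiguous_multi_genus = 1L, genus = 2L,
    species = 3L)[[level]]
}

#' Reconcile the two markers' assignments of one taxon
#'
#' Precedence is by specificity first (species beats genus beats ambiguous
#' beats unidentifiable); at equal specificity the higher-resolution marker
#' (by default \emph{trnH-psbA}) wins. If both markers make species-level
#' calls that disagree, the result carries `conflict = TRUE` and the call
#' of the precedence marker — the disagreement is reported, never silently
#' merged.
#'
#' @param r_rbcl,r_trnh `assignment` objects (either may be `NULL` when a
#'   marker did not detect the taxon; not both).
#' @param precedence Marker that wins ties (default `"trnH-psbA"`).
#' @return An `assignment` with extra fields `source_marker`, `conflict`,
#'   and `components` (the two inputs).
#' @export
reconcile_markers <- function(r_rbcl = NULL, r_trnh = NULL,
                              precedence = "trnH-psbA") {
  if (is.null(r_rbcl) && is.null(r_trnh)) {
    stop("at least one marker assignment must be present", call. = FALSE)
  }
  check_marker(precedence)
  pick <- function(win) {
    out <- unclass(win$assignment)
    out$source_marker <- win$marker
    out$conflict <- FALSE
    out$components <- list(rbcL = r_rbcl, `trnH-psbA` = r_trnh)
    class(out) <- "assignment"
    out
  }
  cands <- list()
  if (!is.null(r_rbcl)) cands <- c(cands, list(list(marker = "rbcL",
                                                    assignment = r_rbcl)))
  if (!is.null(r_trnh)) cands <- c(cands, list(list(marker = "trnH-psbA",
                                                    assignment = r_trnh)))
  if (length(cands) == 1L) return(pick(cands[[1L]]))

  ranks <- vapply(cands, function(c) call_rank(c$assignment$call_level), 0L)
  if (ranks[1L] != ranks[2L]) return(pick(cands[[which.max(ranks)]]))
  pref <- if (cands[[1L]]$marker == precedence) 1L else 2L
  out <- pick(cands[[pref]])
  if (out$call_level == "species" &&
      cands[[1L]]$assignment$call_name != cands[[2L]]$assignment$call_name) {
    out$conflict <- TRUE
    warning("species-level calls disagree between markers: ",
            cands[[1L]]$assignment$call_name, " (rbcL) vs ",
            cands[[2L]]$assignment$call_name, " (trnH-psbA)",
            call. = FALSE)
  }
  out
}

#' Should a MOTU be escalated to an external database search?
#'
#' MOTUs with no qualifying hit in the local reference database are the
#' ones a follow-up search against a global nucleotide database would
#' target; this predicate only flags them (the live query is out of
#' scope).
#'
#' @param result An `assignment`.
#' @return `TRUE` iff the call level is `unidentifiable`.
#' @export
flag_for_external_lookup <- function(result) {
  identical(result$call_level, "unidentifiable")
}
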