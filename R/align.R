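#' Default alignment scoring scheme
#'
#' Match +1, mismatch -1, gap open -2, gap extend -2. Because the open and
#' extend penalties are equal the gap cost is linear in gap length; the
#' aligner requires `gap_open == gap_extend`.
#'
#' @return Named list with elements `match`, `mismatch`, `gap_open`,
#'   `gap_extend`.
#' @export
default_scoring <- function() {
  list(match = 1, mismatch = -1, gap_open = -2, gap_extend = -2)
}

#' @noRd
check_scoring <- function(scoring) {
  need <- c("match", "mismatch", "gap_open", "gap_extend")
  if (!is.list(scoring) || !all(need %in% names(scoring))) {
    stop("`scoring` must be a list with elements ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (scoring$gap_open != scoring$gap_extend) {
    stop("this aligner uses a linear gap penalty: gap_open must equal ",
         "gap_extend", call. = FALSE)
  }
  scoring
}

#' @noRd
band_arg <- function(band) {
  if (is.null(band) || !is.finite(band)) return(-1L)
  band <- as.integer(band)
  if (band < 0L) stop("`band` must be a non-negative integer or NULL",
                      call. = FALSE)
  band
}

#' Semi-global pairwise alignment of two DNA sequences
#'
#' Optimal Needleman-Wunsch alignment with free end gaps (end gap columns
#' contribute nothing to the score), a linear gap penalty, and a fixed,
#' deterministic traceback tie order (diagonal over up over left; among
#' equally scoring end cells the one with the larger row index, then larger
#' column index, wins). IUPAC ambiguity codes are supported: a column is a
#' match iff the two symbols' base sets intersect (so `N` matches
#' everything); a gap never matches. The DP is always run on the
#' lexicographically ordered pair (the gapped strings are swapped back),
#' so identity is exactly symmetric even when co-optimal tracebacks exist.
#'
#' Percent identity is BLAST-like: matches divided by the number of
#' alignment columns excluding end-gap columns (internal gap columns count
#' in the denominator). An exact-but-shorter query therefore still scores
#' identity 1.
#'
#' @param a,b Non-empty IUPAC DNA strings.
#' @param scoring Scoring scheme, see [default_scoring()].
#' @param band Optional half-width of a diagonal band restricting the DP
#'   (plus the length difference of the two sequences). `NULL` (default)
#'   runs the full dynamic program. A banded alignment is exact whenever
#'   the optimal path deviates from the diagonal by at most `band` columns,
#'   which holds for substitution-dominated sequence pairs; it is used by
#'   the pipeline for throughput.
#' @return Object of class `pairwise_alignment`: a list with the gapped
#'   strings `aligned_a`/`aligned_b`, `score`, `matches`, `mismatches`,
#'   `internal_gap_columns`, `end_gap_columns`, `max_internal_gap_run` and
#'   `identity` (fraction in \[0, 1\]).
#' @export
#' @examples
#' aln <- global_align("ACGTACGT", "ACGAACGT")
#' aln$matches   # 7
#' aln$identity  # 0.875
global_align <- function(a, b, scoring = default_scoring(), band = NULL) {
  check_dna(a, "sequence a")
  check_dna(b, "sequence b")
  check_scoring(scoring)
  res <- nw_align_cpp(toupper(a), toupper(b),
                      scoring$match, scoring$mismatch, scoring$gap_extend,
                      band_arg(band), TRUE)
  structure(res, class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise alignment: score %g, identity %.1f%%\n",
              x$score, 100 * x$identity))
  cat(sprintf("  matches %d, mismatches %d, internal gaps %d, end gaps %d\n",
              x$matches, x$mismatches, x$internal_gap_columns,
              x$end_gap_columns))
  if (nchar(x$aligned_a) <= 120) {
    cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  }
  invisible(x)
}

#' Percent identity between two sequences
#'
#' `100 * identity` of the optimal semi-global alignment, unrounded (reports
#' render it to one decimal place for display only).
#'
#' @inheritParams global_align
#' @return Numeric percentage in \[0, 100\].
#' @export
#' @examples
#' percent_identity("ACGT", "ACGT")  # 100
percent_identity <- function(a, b, scoring = default_scoring(), band = NULL) {
  100 * global_align(a, b, scoring = scoring, band = band)$identity
}

#' @noRd
identity_to_refs <- function(query, refs, scoring, band) {
  100 * nw_identity_many_cpp(toupper(query), toupper(refs),
                             scoring$match, scoring$mismatch,
                             scoring$gap_extend, band_arg(band))
}
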