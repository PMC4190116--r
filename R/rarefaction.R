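#' Pool per-clone taxon labels for one site and marker
#'
#' Expands assignment reports into one taxon label per sequenced clone,
#' pooling all sampling dates of a site (pooling removes the influence of
#' phenology differences between dates on the accumulation curve).
#' Identified MOTUs contribute their call name; unidentifiable MOTUs are
#' real sequences of unseen taxa, so by default each contributes a distinct
#' pseudo-label (one per MOTU).
#'
#' @param reports A sample report data frame (or list of them) as produced
#'   by [assign_clone_library()], with columns `site`, `date`, `marker`,
#'   `motu_id`, `n_clones`, `call_level`, `call_name`.
#' @param site Site label (error if absent from the reports).
#' @param marker `"rbcL"` or `"trnH-psbA"`.
#' @param include_unidentified Count unidentifiable MOTUs as distinct
#'   pseudo-taxa (default `TRUE`).
#' @return Character vector of labels, one per clone.
#' @export
pool_site_labels <- function(reports, site, marker,
                             include_unidentified = TRUE) {
  check_marker(marker)
  if (is.data.frame(reports)) reports <- list(reports)
  rep_df <- do.call(rbind, lapply(reports, as.data.frame))
  if (!site %in% rep_df$site) stop("no reports for site: ", site,
                                   call. = FALSE)
  rep_df <- rep_df[rep_df$site == site & rep_df$marker == marker, ,
                   drop = FALSE]
  labels <- character(0)
  for (r in seq_len(nrow(rep_df))) {
    row <- rep_df[r, ]
    if (row$call_level %in% c("unidentifiable", "ambiguous_multi_genus")) {
      if (!include_unidentified) next
      lab <- paste("unidentified", row$site, row$date, row$marker,
                   row$motu_id, sep = ":")
    } else {
      lab <- row$call_name
    }
    labels <- c(labels, rep(lab, row$n_clones))
  }
  labels
}

#' Species-accumulation curve by randomized resampling
#'
#' Mean (and spread) of the running distinct-taxon count over `n_iter`
#' uniformly random orderings of the pooled clone labels — an
#' individual-based accumulation curve with clones as individuals.
#'
#' @param labels Character vector, one taxon label per clone.
#' @param n_iter Number of random orderings (default 1000).
#' @param seed Integer seed; the curve is deterministic given it.
#' @return Object of class `accumulation_curve`: data frame with columns
#'   `depth`, `mean_richness`, `sd_richness`; attributes `method`
#'   (`"permutation"`) and `n_iterations`.
#' @export
accumulation_permutation <- function(labels, n_iter = 1000L, seed = 1L) {
  if (length(labels) == 0) stop("`labels` must be non-empty", call. = FALSE)
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) stop("n_iter must be >= 1", call. = FALSE)
  n <- length(labels)
  withr::with_seed(seed, {
    acc <- matrix(0L, nrow = n_iter, ncol = n)
    for (it in seq_len(n_iter)) {
      perm <- sample(labels)
      acc[it, ] <- cumsum(!duplicated(perm))
    }
  })
  out <- data.frame(depth = seq_len(n),
                    mean_richness = colMeans(acc),
                    sd_richness = apply(acc, 2L, stats::sd))
  if (n_iter == 1L) out$sd_richness <- 0
  structure(out, class = c("accumulation_curve", "data.frame"),
            method = "permutation", n_iterations = n_iter)
}

#' Analytic (hypergeometric) species-accumulation curve
#'
#' Closed-form expectation of the number of distinct taxa in a uniform
#' random subsample of n clones from an abundance vector:
#' E\[S(n)\] = sum_i (1 - choose(N - N_i, n) / choose(N, n)) with
#' N = sum_i N_i — classic individual-based rarefaction. Binomial
#' coefficients are computed in log space so large N does not overflow.
#'
#' @param abundance Integer vector of per-taxon clone counts (all >= 1).
#' @param depths Depths at which to evaluate (default 1..N).
#' @return An `accumulation_curve` data frame (`sd_richness` is the exact
#'   standard deviation of zero at full depth and is reported as `NA` at
#'   partial depths; the method attribute is `"analytic"`).
#' @export
accumulation_analytic <- function(abundance, depths = NULL) {
  abundance <- as.numeric(abundance)
  if (length(abundance) == 0 || any(abundance < 1)) {
    stop("abundances must all be >= 1", call. = FALSE)
  }
  N <- sum(abundance)
  if (is.null(depths)) depths <- seq_len(N)
  if (any(depths < 1) || any(depths > N)) {
    stop("depths must lie in 1..N (N = ", N, ")", call. = FALSE)
  }
  mean_richness <- vapply(depths, function(n) {
    sum(1 - exp(lchoose(N - abundance, n) - lchoose(N, n)))
  }, 0)
  structure(data.frame(depth = depths, mean_richness = mean_richness,
                       sd_richness = NA_real_),
            class = c("accumulation_curve", "data.frame"),
            method = "analytic", n_iterations = NA_integer_)
}

#' @export
print.accumulation_curve <- function(x, ...) {
  cat(sprintf("accumulation_curve (%s): %d depths, final richness %g\n",
              attr(x, "method"), nrow(x),
              x$mean_richness[nrow(x)]))
  invisible(x)
}

#' Write an accumulation curve as TSV
#'
#' @param curve An `accumulation_curve`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_accumulation_curve <- function(curve, path) {
  write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
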