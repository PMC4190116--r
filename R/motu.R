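#' Cluster clone reads into MOTUs
#'
#' Single-linkage clustering of near-identical reads: two reads link iff
#' their optimal end-to-end (global) alignment has at most `max_mismatches`
#' mismatch columns and no gap run longer than `max_mismatches`. End-to-end
#' alignment is used for dereplication — under the free-end-gap semantics
#' used for reference matching, two unrelated reads could "link" through a
#' short perfectly matching overlap. The default
#' radius of 2 mismatches matches the clone error model (1-2 substitutions
#' per clone); with `max_mismatches = 0` the operation is exact
#' dereplication. Because linkage is single, chains of reads can connect
#' sequences further apart than the radius; this is accepted behaviour.
#'
#' The representative of a MOTU is its most frequent exact sequence
#' (ties broken to the lexicographically smallest); MOTUs are ordered by
#' descending clone count, then lexicographic representative, making the
#' result invariant to input order.
#'
#' @param reads A `clone_library` (all reads must share site, date and
#'   marker).
#' @param max_mismatches Linkage radius in mismatch columns.
#' @param scoring,band Alignment settings (see [global_align()]).
#' @return Object of class `motu_set`: a list of `motu` objects, each a
#'   list with `motu_id`, `members` (rows of `reads`), `representative`,
#'   `consensus` and `n_clones`; sample annotation in attributes `site`,
#'   `date`, `marker`.
#' @export
cluster_motus <- function(reads, max_mismatches = 2L,
                          scoring = default_scoring(), band = NULL) {
  if (nrow(reads) == 0) {
    return(structure(list(), class = "motu_set",
                     site = NA_character_, date = NA_character_,
                     marker = NA_character_))
  }
  if (length(unique(reads$site)) > 1L || length(unique(reads$date)) > 1L ||
      length(unique(reads$marker)) > 1L) {
    stop("all reads must share one (site, date, marker)", call. = FALSE)
  }
  check_scoring(scoring)
  max_mismatches <- as.integer(max_mismatches)

  # linkage on distinct sequences only; exact duplicates always co-cluster
  useq <- sort(unique(reads$sequence))
  if (max_mismatches == 0L && identical(band, NULL)) {
    linked <- diag(length(useq)) == 1
  } else {
    linked <- nw_link_pairs_cpp(useq, max_mismatches,
                                scoring$match, scoring$mismatch,
                                scoring$gap_extend, band_arg(band))
  }
  comp <- connected_components(linked)

  motus <- lapply(split(seq_along(useq), comp), function(ix) {
    member_rows <- reads[reads$sequence %in% useq[ix], , drop = FALSE]
    tab <- table(member_rows$sequence)
    rep_seq <- sort(names(tab)[tab == max(tab)])[1L]
    list(members = member_rows, representative = rep_seq,
         n_clones = nrow(member_rows))
  })
  ord <- order(-vapply(motus, `[[`, 0L, "n_clones"),
               vapply(motus, `[[`, "", "representative"), method = "radix")
  motus <- motus[ord]
  motus <- lapply(seq_along(motus), function(i) {
    m <- motus[[i]]
    m$motu_id <- sprintf("MOTU%03d", i)
    m <- m[c("motu_id", "members", "representative", "n_clones")]
    m$consensus <- NULL
    class(m) <- "motu"
    m$consensus <- motu_consensus(m, scoring = scoring, band = band)
    m
  })
  structure(motus, class = "motu_set",
            site = reads$site[1L], date = reads$date[1L],
            marker = reads$marker[1L])
}

#' @noRd
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier) > 0) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

#' Consensus sequence of a MOTU
#'
#' Column-wise majority over the members. When all members have equal
#' length the stack is gapless and the majority is taken per position; with
#' unequal lengths each member is aligned to the representative and its
#' bases are projected onto the representative's coordinates (insertions
#' relative to the representative are ignored; positions whose majority is
#' a gap are dropped). All ties resolve toward the representative's base,
#' so the consensus does not depend on member order.
#'
#' @param motu A `motu` (from [cluster_motus()]) with at least one member.
#' @param scoring,band Alignment settings used for unequal-length stacks.
#' @return The consensus sequence string.
#' @export
motu_consensus <- function(motu, scoring = default_scoring(), band = NULL) {
  seqs <- motu$members$sequence
  if (length(seqs) == 0) stop("empty MOTU has no consensus", call. = FALSE)
  rep_seq <- motu$representative
  rep_chars <- strsplit(rep_seq, "")[[1L]]
  L <- length(rep_chars)
  if (all(nchar(seqs) == L)) {
    mat <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                  nrow = length(seqs), byrow = TRUE)
  } else {
    mat <- matrix("-", nrow = length(seqs), ncol = L)
    for (i in seq_along(seqs)) {
      if (seqs[i] == rep_seq) { mat[i, ] <- rep_chars; next }
      aln <- global_align(seqs[i], rep_seq, scoring = scoring, band = band)
      aa <- strsplit(aln$aligned_a, "")[[1L]]
      ab <- strsplit(aln$aligned_b, "")[[1L]]
      mat[i, cumsum(ab != "-")[ab != "-"]] <- aa[ab != "-"]
    }
  }
  cons <- vapply(seq_len(L), function(j) {
    tab <- table(mat[, j])
    top <- names(tab)[tab == max(tab)]
    if (rep_chars[j] %in% top) rep_chars[j] else sort(top)[1L]
  }, "")
  paste(cons[cons != "-"], collapse = "")
}

#' @export
print.motu_set <- function(x, ...) {
  cat(sprintf("motu_set: %d MOTUs from %s / %s / %s\n", length(x),
              attr(x, "site"), attr(x, "date"), attr(x, "marker")))
  if (length(x) > 0) print(head(as.data.frame(x), 10L))
  invisible(x)
}

#' @export
as.data.frame.motu_set <- function(x, ...) {
  if (length(x) == 0) {
    return(data.frame(motu_id = character(), site = character(),
                      date = character(), marker = character(),
                      n_clones = integer(), representative = character(),
                      consensus = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    motu_id = vapply(x, `[[`, "", "motu_id"),
    site = attr(x, "site"), date = attr(x, "date"),
    marker = attr(x, "marker"),
    n_clones = vapply(x, `[[`, 0L, "n_clones"),
    representative = vapply(x, `[[`, "", "representative"),
    consensus = vapply(x, `[[`, "", "consensus"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Write MOTUs as consensus FASTA plus a summary TSV
#'
#' @param motus A `motu_set`.
#' @param fasta_path,tsv_path Output paths.
#' @return Invisibly, the summary data frame.
#' @export
write_motus <- function(motus, fasta_path, tsv_path) {
  df <- as.data.frame(motus)
  seqs <- Biostrings::DNAStringSet(setNames(df$consensus, df$motu_id))
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80L)
  write.table(df[c("motu_id", "site", "date", "marker", "n_clones")],
              tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
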