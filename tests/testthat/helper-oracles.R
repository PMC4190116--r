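# Independent oracles used to validate the aligner and the clustering.
# These deliberately share no code with the package: pure-R formulations
# of the same alignment problems.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

iupac_match <- function(x, y) {
  length(intersect(IUPAC_SETS[[x]], IUPAC_SETS[[y]])) > 0
}

# Memoized recursive enumeration of every semi-global alignment:
# a path may start after skipping a prefix of one sequence (free), advances
# by diagonal/up/left moves, and may stop once either sequence is exhausted
# (the remaining suffix of the other is a free end gap). Enumerates the
# same move space as the DP but from the opposite direction.
oracle_semiglobal_score <- function(a, b, match = 1, mismatch = -1,
                                    gap = -2) {
  av <- strsplit(toupper(a), "")[[1L]]
  bv <- strsplit(toupper(b), "")[[1L]]
  m <- length(av); n <- length(bv)
  memo <- matrix(NA_real_, m + 1L, n + 1L)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1L, j + 1L])) return(memo[i + 1L, j + 1L])
    best <- if (i == m || j == n) 0 else -Inf
    if (i < m && j < n) {
      s <- if (iupac_match(av[i + 1L], bv[j + 1L])) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L))
    }
    if (i < m) best <- max(best, gap + rec(i + 1L, j))
    if (j < n) best <- max(best, gap + rec(i, j + 1L))
    memo[i + 1L, j + 1L] <<- best
    best
  }
  starts <- c(vapply(0:m, function(i0) rec(i0, 0L), 0),
              vapply(0:n, function(j0) rec(0L, j0), 0))
  max(starts)
}

# Recompute the score of a returned alignment from its gapped strings,
# with maximal end runs of gap columns scored 0 (free end gaps).
score_from_alignment <- function(aligned_a, aligned_b, match = 1,
                                 mismatch = -1, gap = -2) {
  ca <- strsplit(aligned_a, "")[[1L]]
  cb <- strsplit(aligned_b, "")[[1L]]
  stopifnot(length(ca) == length(cb))
  is_gap <- ca == "-" | cb == "-"
  L <- length(ca)
  lead <- if (all(is_gap)) L else which.min(is_gap) - 1L
  trail <- if (all(is_gap)) 0L else L - max(which(!is_gap))
  core <- seq_len(L)
  core <- core[core > lead & core <= L - trail]
  sc <- 0
  for (k in core) {
    sc <- sc + if (is_gap[k]) gap
    else if (iupac_match(ca[k], cb[k])) match else mismatch
  }
  sc
}

# Independent global (penalized-end) alignment with the package's stated
# tie order (diagonal > up > left), returning the counts the MOTU linkage
# predicate uses. Row-wise DP with a running-maximum scan for the
# left-dependency; traceback over the completed score matrix.
oracle_global_counts <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(toupper(a), "")[[1L]]
  bv <- strsplit(toupper(b), "")[[1L]]
  m <- length(av); n <- length(bv)
  H <- matrix(0, m + 1L, n + 1L)
  H[1L, ] <- gap * (0:n)
  H[, 1L] <- gap * (0:m)
  smat <- outer(av, bv, Vectorize(function(x, y)
    if (iupac_match(x, y)) match else mismatch))
  for (i in seq_len(m)) {
    t_row <- pmax(H[i, 1:n] + smat[i, ], H[i, 2:(n + 1L)] + gap)
    acc <- Reduce(function(prev, x) max(x, prev + gap), t_row,
                  accumulate = TRUE, init = H[i + 1L, 1L])
    H[i + 1L, ] <- acc
  }
  # traceback with diag > up > left priority
  i <- m; j <- n
  mism <- 0L; run <- 0L; max_run <- 0L
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L) {
      here <- H[i + 1L, j + 1L]
      if (here == H[i, j] + smat[i, j]) {
        if (!iupac_match(av[i], bv[j])) mism <- mism + 1L
        run <- 0L
        i <- i - 1L; j <- j - 1L
        next
      }
      if (here == H[i, j + 1L] + gap) {
        run <- run + 1L; max_run <- max(max_run, run)
        i <- i - 1L
        next
      }
      run <- run + 1L; max_run <- max(max_run, run)
      j <- j - 1L
    } else if (i > 0L) {
      run <- run + 1L; max_run <- max(max_run, run)
      i <- i - 1L
    } else {
      run <- run + 1L; max_run <- max(max_run, run)
      j <- j - 1L
    }
  }
  list(score = H[m + 1L, n + 1L], mismatches = mism, max_gap_run = max_run)
}

# Brute-force single-linkage clustering: oracle adjacency, then transitive
# closure by repeated boolean matrix multiplication.
oracle_single_linkage <- function(seqs, max_mismatch = 2L) {
  n <- length(seqs)
  adj <- diag(n) == 1
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      # same pair canonicalization as the aligner (symmetry of the predicate)
      pair <- sort(c(seqs[i], seqs[j]))
      o <- oracle_global_counts(pair[1L], pair[2L])
      linked <- o$mismatches <= max_mismatch && o$max_gap_run <= max_mismatch
      adj[i, j] <- linked
      adj[j, i] <- linked
    }
  }
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0 | reach
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  # canonical partition: sorted list of sorted member index sets
  groups <- unique(apply(reach, 1L, function(r) paste(which(r),
                                                      collapse = ",")))
  sort(groups)
}

# canonical partition of a motu_set, as read indices into the input library
partition_of_motus <- function(motus, reads) {
  groups <- vapply(motus, function(m) {
    paste(sort(match(m$members$read_id, reads$read_id)), collapse = ",")
  }, "")
  sort(groups)
}
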