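# Shared sequence helpers for tests (independent of package internals).

BASES <- c("A", "C", "G", "T")

rand_dna <- function(len) paste(sample(BASES, len, replace = TRUE),
                                collapse = "")

# k substitutions at given (or random) positions; base always changes
substitute_at <- function(seq, k = NULL, positions = NULL) {
  chars <- strsplit(seq, "")[[1L]]
  if (is.null(positions)) positions <- sample(length(chars), k)
  for (p in positions) {
    chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

make_library <- function(seqs, site = "S1", date = "D1", marker = "rbcL",
                         truth = NA_character_) {
  n <- length(seqs)
  structure(data.frame(
    read_id = sprintf("r%03d", seq_len(n)),
    site = rep_len(site, n), date = rep_len(date, n),
    marker = rep_len(marker, n),
    sequence = seqs,
    truth_species = rep_len(truth, n),
    is_contaminant = rep_len(FALSE, n),
    stringsAsFactors = FALSE
  ), class = c("clone_library", "data.frame"))
}

# tiny two-marker reference database around explicit sequences
make_refdb <- function(species, rbcl_seqs, trnh_seqs = NULL,
                       status = "common") {
  if (is.null(trnh_seqs)) trnh_seqs <- rbcl_seqs
  reference_db(
    record_id = c(paste0("R", seq_along(species)),
                  paste0("T", seq_along(species))),
    species = c(species, species),
    marker = rep(c("rbcL", "trnH-psbA"), each = length(species)),
    sequence = c(rbcl_seqs, trnh_seqs),
    status = rep_len(status, 2L * length(species)),
    accession = ""
  )
}
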