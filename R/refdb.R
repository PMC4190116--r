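#' Construct a two-marker barcode reference database
#'
#' A reference database is a data frame with one row per reference record
#' (one marker sequence of one species) and columns `record_id`, `species`,
#' `genus`, `marker`, `status`, `accession`, `sequence`. The genus is always
#' the first whitespace-delimited token of the species name (subspecific
#' epithets are kept verbatim in the species string). Each (species, marker)
#' pair may appear at most once.
#'
#' @param record_id Character vector of unique record identifiers.
#' @param species Species binomials (optionally with subspecific epithet).
#' @param marker `"rbcL"` or `"trnH-psbA"`, per record.
#' @param sequence Uppercase IUPAC DNA strings (lowercase and `U` are
#'   normalized on construction).
#' @param status Per-record status in the study area: `"common"`, `"rare"`
#'   or `"alien"`.
#' @param accession Optional accession strings ("" if none).
#' @return Object of class `reference_db` (a data frame).
#' @export
reference_db <- function(record_id, species, marker, sequence,
                         status = "common", accession = "") {
  n <- length(record_id)
  df <- data.frame(
    record_id = as.character(record_id),
    species = as.character(species),
    genus = vapply(strsplit(as.character(species), "\\s+"), `[`, "", 1L),
    marker = rep_len(as.character(marker), n),
    status = rep_len(as.character(status), n),
    accession = rep_len(as.character(accession), n),
    sequence = normalize_dna(as.character(sequence)),
    stringsAsFactors = FALSE
  )
  validate_reference_db(df)
}

#' @noRd
validate_reference_db <- function(df) {
  if (nrow(df) > 0) {
    if (anyDuplicated(df$record_id)) {
      stop("duplicate record_id: ",
           df$record_id[duplicated(df$record_id)][1L], call. = FALSE)
    }
    bad_marker <- !df$marker %in% MARKERS
    if (any(bad_marker)) {
      stop("invalid marker '", df$marker[bad_marker][1L],
           "' for record ", df$record_id[bad_marker][1L], call. = FALSE)
    }
    bad_status <- !df$status %in% STATUS_LEVELS
    if (any(bad_status)) {
      stop("invalid status '", df$status[bad_status][1L],
           "' for record ", df$record_id[bad_status][1L], call. = FALSE)
    }
    check_dna(df$sequence, "sequence of record")
    key <- paste(df$species, df$marker, sep = "\r")
    if (anyDuplicated(key)) {
      d <- df[duplicated(key), , drop = FALSE]
      stop("duplicate (species, marker) pair: ", d$species[1L], " / ",
           d$marker[1L], call. = FALSE)
    }
    tok1 <- vapply(strsplit(df$species, "\\s+"), `[`, "", 1L)
    if (!all(df$genus == tok1)) {
      stop("genus must equal the first token of species", call. = FALSE)
    }
  }
  class(df) <- c("reference_db", "data.frame")
  df
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("reference_db: %d records, %d species (rbcL: %d, trnH-psbA: %d)\n",
              nrow(x), length(unique(x$species)),
              sum(x$marker == "rbcL"), sum(x$marker == "trnH-psbA")))
  if (nrow(x) > 0) print(head(as.data.frame(x)[c("record_id", "species",
                                                 "marker", "status")], 6L))
  invisible(x)
}

#' Subset reference records by marker
#'
#' @param db A `reference_db`.
#' @param marker `"rbcL"` or `"trnH-psbA"`.
#' @return The rows of `db` for that marker.
#' @export
refs_for_marker <- function(db, marker) {
  check_marker(marker)
  db[db$marker == marker, , drop = FALSE]
}

#' Read a reference database from FASTA plus a metadata TSV
#'
#' The FASTA id (first whitespace-delimited token of the header) is the join
#' key into the metadata table, a TSV with columns exactly `record_id`,
#' `species`, `marker`, `status`, `accession`. Sequences are uppercased and
#' `U` is normalized to `T` on read; both single-line and wrapped FASTA are
#' accepted.
#'
#' @param fasta_path Path to the sequence FASTA.
#' @param metadata_path Path to the metadata TSV.
#' @return A [reference_db()].
#' @export
read_reference <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE,
                     colClasses = "character")
  need <- c("record_id", "species", "marker", "status", "accession")
  if (!identical(names(meta), need)) {
    stop("metadata TSV must have columns exactly: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(ids, meta$record_id)
  if (length(missing) > 0) {
    stop("FASTA id not found in metadata: ", missing[1L], call. = FALSE)
  }
  meta <- meta[match(ids, meta$record_id), , drop = FALSE]
  reference_db(record_id = ids, species = meta$species,
               marker = meta$marker, sequence = as.character(seqs),
               status = meta$status, accession = meta$accession)
}

#' Write a reference database to FASTA plus a metadata TSV
#'
#' Records are written sorted by (species, marker) so output is byte-stable;
#' FASTA is wrapped at 80 columns.
#'
#' @param db A `reference_db`.
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, `db` in the written (sorted) order.
#' @export
write_reference <- function(db, fasta_path, metadata_path) {
  db <- validate_reference_db(as.data.frame(db))
  ord <- order(db$species, db$marker, method = "radix")
  db <- db[ord, , drop = FALSE]
  rownames(db) <- NULL
  seqs <- Biostrings::DNAStringSet(setNames(db$sequence, db$record_id))
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80L)
  write.table(as.data.frame(db)[c("record_id", "species", "marker",
                                  "status", "accession")],
              metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(db)
}

#' Screen an rbcL record for pseudogene signatures
#'
#' \emph{rbcL} is protein-coding, so a nuclear pseudogene copy typically
#' shows a reading-frame disruption: either the sequence length is not a
#' whole number of codons in the stated frame (`frameshift_indel`, checked
#' first) or the translation contains a stop codon before the final codon
#' (`internal_stop`). The reading frame implied by the amplification primers
#' is an explicit parameter. The screen is undefined for the non-coding
#' \emph{trnH-psbA} spacer and errors there. Codons containing ambiguity
#' codes are not counted as stops.
#'
#' @param record One row of a `reference_db` (or any list with `marker` and
#'   `sequence`).
#' @param frame Reading frame offset, 0, 1 or 2.
#' @return `"pass"`, `"internal_stop"` or `"frameshift_indel"`.
#' @export
screen_rbcl_pseudogene <- function(record, frame = 0L) {
  if (!identical(as.character(record$marker), "rbcL")) {
    stop("pseudogene screen is defined only for rbcL ",
         "(trnH-psbA is a non-coding spacer)", call. = FALSE)
  }
  if (!frame %in% 0:2) stop("`frame` must be 0, 1 or 2", call. = FALSE)
  seq <- normalize_dna(as.character(record$sequence))
  if (nchar(seq) < 3L) stop("sequence must be at least one codon",
                            call. = FALSE)
  if ((nchar(seq) - frame) %% 3L != 0L) return("frameshift_indel")
  n_codons <- (nchar(seq) - frame) %/% 3L
  if (n_codons >= 2L) {
    starts <- frame + 3L * (seq_len(n_codons - 1L) - 1L) + 1L
    codons <- substring(seq, starts, starts + 2L)
    if (any(codons %in% c("TAA", "TAG", "TGA"))) return("internal_stop")
  }
  "pass"
}
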