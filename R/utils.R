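# Shared helpers: condition constructors, sequence utilities, FASTA/FASTQ IO
# wrappers around Biostrings, and commented-header TSV IO used by every stage.

DNA_BASES <- c("A", "C", "G", "T")

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("teshot_validation_error", "error")))
}

stop_dependency <- function(...) {
  stop(errorCondition(paste0(...), class = c("teshot_dependency_error", "error")))
}

#' Draw a random DNA sequence
#'
#' Bases are i.i.d. uniform over A, C, G, T.
#'
#' @param length Sequence length in bp.
#' @return A single character string.
#' @export
random_dna <- function(length) {
  if (length < 0) stop_validation("length must be non-negative")
  paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) cpp_revcomp(x)

## phred+33 encoding helpers
phred_to_chars <- function(q) {
  intToUtf8(pmin(pmax(q, 0), 93) + 33L, multiple = FALSE)
}

chars_to_phred <- function(s) {
  utf8ToInt(s) - 33L
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a read set to FASTQ (phred+33)
#'
#' @param reads A `read_set` data frame (columns `read_id`, `sequence`,
#'   `quality`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  q <- Biostrings::BStringSet(reads$quality)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ file.
#' @param library_id Library label attached to every read.
#' @return A `read_set` data frame.
#' @export
read_fastq <- function(path, library_id = NA_character_) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  read_set(
    read_id = names(x),
    sequence = as.character(x),
    quality = as.character(S4Vectors::mcols(x)$qualities),
    mate = NA_integer_,
    library_id = library_id
  )
}

#' Construct a read set
#'
#' A read set is a plain data frame with one row per read: identifier,
#' sequence, phred+33 quality string, mate (1, 2 or NA for unpaired) and
#' library label.
#'
#' @param read_id,sequence,quality,mate,library_id Column vectors.
#' @return A data frame of class `read_set`.
#' @export
read_set <- function(read_id, sequence, quality, mate = NA_integer_,
                     library_id = NA_character_) {
  if (length(sequence) && any(nchar(sequence) != nchar(quality)))
    stop_validation("sequence and quality lengths differ")
  out <- data.frame(
    read_id = as.character(read_id),
    sequence = as.character(sequence),
    quality = as.character(quality),
    mate = rep_len(as.integer(mate), length(read_id)),
    library_id = rep_len(as.character(library_id), length(read_id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("read_set", "data.frame")
  out
}

## TSV with '#'-prefixed metadata header lines
write_tsv <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    for (nm in names(meta))
      writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

## derive a bounded child seed from (seed, index); stays below 2^31
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483629
}
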