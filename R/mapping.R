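# Read placement on reference contigs: a seed-and-extend aligner with exact
# k-mer seeding and full-length ungapped extension, SAM interoperability and
# per-position pileups. Multi-mapping reads are placed uniformly at random
# among equal-best placements so multi-copy families still accumulate their
# full coverage.

#' Build a reference contig set
#'
#' @param sequences Named character vector of contig sequences.
#' @param category Per-contig category: `"TE"`, `"UCOS"` or `"other"`.
#' @param te_class Per-contig TE class (`"I"`, `"II"` or `NA`).
#' @param superfamily Per-contig superfamily label (required for TE contigs).
#' @return A `reference_contigs` data frame.
#' @export
reference_contigs <- function(sequences, category = "TE", te_class = NA,
                              superfamily = NA) {
  if (length(sequences) == 0 || any(nchar(sequences) == 0))
    stop_validation("contig sequences must be non-empty")
  if (is.null(names(sequences))) stop_validation("contigs must be named")
  out <- data.frame(contig_id = names(sequences),
                    sequence = unname(as.character(sequences)),
                    category = rep_len(category, length(sequences)),
                    te_class = rep_len(as.character(te_class), length(sequences)),
                    superfamily = rep_len(as.character(superfamily),
                                          length(sequences)),
                    stringsAsFactors = FALSE)
  if (any(out$category == "TE" & is.na(out$superfamily)))
    stop_validation("TE contigs need a superfamily label")
  class(out) <- c("reference_contigs", "data.frame")
  out
}

#' Build an exact k-mer seed index over reference contigs
#'
#' Indexes every k-mer of both strands of every contig.
#'
#' @param contigs A `reference_contigs` object (or named character vector).
#' @param k Seed length (8--31).
#' @return A `seed_index`.
#' @export
build_index <- function(contigs, k = 13) {
  if (!inherits(contigs, "reference_contigs"))
    contigs <- reference_contigs(contigs)
  if (k < 8 || k > 31) stop_validation("k must be in [8, 31]")
  ptr <- cpp_build_index(contigs$contig_id, toupper(contigs$sequence), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), contigs = contigs),
            class = "seed_index")
}

#' Look up a k-mer in a seed index
#'
#' Returns every indexed occurrence: contig, 0-based position of the k-mer
#' on the forward strand, and the strand on which it matches.
#'
#' @param index A `seed_index`.
#' @param kmer k-mer string of the index's k.
#' @return Data frame with `contig`, `pos`, `strand`.
#' @export
index_lookup <- function(index, kmer) {
  hits <- cpp_index_lookup(index$ptr, toupper(kmer))
  hits$contig <- index$contigs$contig_id[hits$contig]
  hits
}

#' Map reads to reference contigs
#'
#' Seeds each read at evenly spaced offsets, extends every candidate
#' placement ungapped across the full read, and keeps the fewest-mismatch
#' placement if its mismatch count is at most
#' `ceiling(max_mismatch_rate * read_length)`. Among equal-best placements one
#' is chosen uniformly at random (reproducible under `set.seed()`); such
#' records get `mapq = 0`, unique ones `mapq = 37`. Reads are treated as
#' single-end.
#'
#' @param reads A `read_set` (or character vector of sequences).
#' @param index A `seed_index`.
#' @param max_mismatch_rate Maximum tolerated mismatch fraction (default
#'   0.08; use [map_params()] presets for the relaxed mode).
#' @param n_seeds Number of seed offsets per read.
#' @return An `alignments` data frame: `read_id`, `contig_id`, `start`
#'   (0-based), `strand`, `aligned_length`, `mismatches`, `mapq`, plus the
#'   `read` index into the supplied read set.
#' @export
map_reads <- function(reads, index, max_mismatch_rate = 0.08, n_seeds = 4) {
  seqs <- if (is.character(reads)) reads else reads$sequence
  ids <- if (is.character(reads)) {
    if (is.null(names(reads))) sprintf("read%d", seq_along(reads)) else names(reads)
  } else reads$read_id
  hits <- cpp_map_reads(index$ptr, toupper(seqs), max_mismatch_rate,
                        as.integer(n_seeds))
  out <- data.frame(
    read = hits$read,
    read_id = ids[hits$read],
    contig_id = index$contigs$contig_id[hits$contig],
    contig = hits$contig,
    start = hits$start,
    strand = ifelse(hits$strand == 1, "-", "+"),
    aligned_length = nchar(seqs)[hits$read],
    mismatches = hits$mismatches,
    mapq = ifelse(hits$n_best > 1, 0L, 37L),
    stringsAsFactors = FALSE
  )
  attr(out, "n_reads") <- length(seqs)
  attr(out, "n_unmapped") <- length(seqs) - nrow(out)
  class(out) <- c("alignments", "data.frame")
  out
}

#' Relaxed / default mapping parameter presets
#'
#' The default preset mirrors stringent short-read alignment; the relaxed
#' preset raises the mismatch ceiling for mapping divergent reads to
#' conserved element regions.
#'
#' @param mode `"default"` or `"relaxed"`.
#' @return List with `max_mismatch_rate` and `n_seeds`.
#' @export
map_params <- function(mode = c("default", "relaxed")) {
  mode <- match.arg(mode)
  if (mode == "default") list(max_mismatch_rate = 0.08, n_seeds = 4)
  else list(max_mismatch_rate = 0.15, n_seeds = 6)
}

#' Export alignments as SAM text
#'
#' Minimal dialect: `@SQ` header lines plus mapped records with FLAG, POS
#' (1-based), ungapped CIGAR and an `NM` tag.
#'
#' @param alignments An `alignments` data frame.
#' @param reads The `read_set` the alignments refer to.
#' @param contigs The `reference_contigs` mapped against.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_sam <- function(alignments, reads, contigs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", contigs$contig_id,
                     nchar(contigs$sequence)), con)
  if (nrow(alignments) > 0) {
    seqs <- reads$sequence[alignments$read]
    quals <- reads$quality[alignments$read]
    rc <- alignments$strand == "-"
    seqs[rc] <- revcomp(seqs[rc])
    quals[rc] <- vapply(strsplit(quals[rc], ""), function(x)
      paste(rev(x), collapse = ""), "")
    flag <- ifelse(rc, 16L, 0L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                       alignments$read_id, flag, alignments$contig_id,
                       alignments$start + 1L, alignments$mapq,
                       alignments$aligned_length, seqs, quals,
                       alignments$mismatches), con)
  }
  invisible(path)
}

#' Import alignments from SAM text
#'
#' Converts mapped primary records (CIGAR consumed to the reference-aligned
#' length; `NM` kept when present); unmapped and secondary records are
#' skipped and counted. Coordinates become 0-based internally.
#'
#' @param path SAM file.
#' @param contigs `reference_contigs` the SAM refers to.
#' @return An `alignments` data frame with attributes `n_skipped_unmapped`
#'   and `n_skipped_secondary`; the imported read sequences/qualities are
#'   attached as attribute `reads`.
#' @export
import_sam <- function(path, contigs) {
  lines <- readLines(path)
  hdr <- grepl("^@", lines)
  sq <- lines[grepl("^@SQ", lines)]
  sq_names <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  unknown <- setdiff(sq_names, contigs$contig_id)
  if (length(unknown) > 0)
    stop_validation("unknown reference name in SAM header: ", unknown[1])
  rec <- lines[!hdr]
  n_unmapped <- 0L; n_secondary <- 0L
  rows <- list(); rseq <- character(0); rqual <- character(0); rid <- character(0)
  for (i in seq_along(rec)) {
    f <- strsplit(rec[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) stop_validation("malformed SAM record at line ",
                                        which(!hdr)[i])
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0) { n_unmapped <- n_unmapped + 1L; next }
    if (bitwAnd(flag, 256L) > 0 || bitwAnd(flag, 2048L) > 0) {
      n_secondary <- n_secondary + 1L; next
    }
    if (!(f[3] %in% contigs$contig_id))
      stop_validation("unknown reference name: ", f[3])
    cigar <- f[6]
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    if (length(ops) == 0) stop_validation("malformed CIGAR at line ",
                                          which(!hdr)[i])
    opn <- as.integer(sub("[A-Z=]$", "", ops))
    opc <- sub("^[0-9]+", "", ops)
    ref_len <- sum(opn[opc %in% c("M", "D", "N", "=", "X")])
    nm <- regmatches(rec[i], regexpr("NM:i:[0-9]+", rec[i]))
    nm <- if (length(nm)) as.integer(sub("NM:i:", "", nm)) else NA_integer_
    strand <- if (bitwAnd(flag, 16L) > 0) "-" else "+"
    s <- f[10]; q <- f[11]
    if (strand == "-") { # store reads in original orientation
      s <- revcomp(s)
      q <- paste(rev(strsplit(q, "")[[1]]), collapse = "")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = f[1], contig_id = f[3], start = as.integer(f[4]) - 1L,
      strand = strand, aligned_length = ref_len, mismatches = nm,
      mapq = as.integer(f[5]), stringsAsFactors = FALSE)
    rid <- c(rid, f[1]); rseq <- c(rseq, s); rqual <- c(rqual, q)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(0), contig_id = character(0),
               start = integer(0), strand = character(0),
               aligned_length = integer(0), mismatches = integer(0),
               mapq = integer(0), stringsAsFactors = FALSE)
  out$read <- seq_len(nrow(out))
  out$contig <- match(out$contig_id, contigs$contig_id)
  attr(out, "n_skipped_unmapped") <- n_unmapped
  attr(out, "n_skipped_secondary") <- n_secondary
  attr(out, "reads") <- read_set(rid, rseq, rqual)
  class(out) <- c("alignments", "data.frame")
  out
}

#' Build per-position pileups and coverage arrays
#'
#' For every contig, `coverage[p]` counts all aligned bases covering `p`
#' (regardless of quality), and `counts` tallies A/C/G/T support restricted
#' to bases with phred quality at least `min_base_quality` (minus-strand
#' alignments contribute the reverse-complemented read). The sum of a
#' contig's coverage equals the summed aligned length of its alignments.
#'
#' @param alignments An `alignments` data frame.
#' @param reads The `read_set` the alignments refer to (ignored for
#'   [import_sam()] output, which carries its reads).
#' @param contigs The `reference_contigs`.
#' @param min_base_quality Phred threshold for the allele tallies.
#' @return A `pileup` list: per contig, `coverage` (integer vector) and
#'   `counts` (4 x length matrix).
#' @export
pileup <- function(alignments, reads = NULL, contigs, min_base_quality = 20) {
  if (is.null(reads)) reads <- attr(alignments, "reads")
  if (is.null(reads)) stop_validation("pileup needs the read set")
  res <- cpp_pileup(nchar(contigs$sequence),
                    alignments$contig, alignments$start,
                    as.integer(alignments$strand == "-"), alignments$read,
                    toupper(reads$sequence), reads$quality,
                    as.integer(min_base_quality))
  names(res) <- contigs$contig_id
  structure(list(columns = res, contigs = contigs,
                 min_base_quality = min_base_quality),
            class = "pileup")
}
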