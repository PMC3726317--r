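# Read preparation: quality end-trimming at a fixed phred threshold and the
# reduced, equalized replicate datasets used by the diversity and PCA stages.

#' Trim low-quality bases from read ends
#'
#' Iteratively removes terminal bases with phred quality below `q_min` from
#' both ends until both terminal bases meet the threshold (equivalently, the
#' maximal low-quality prefix and suffix are removed). Interior low-quality
#' bases are retained. Reads trimmed to length zero are dropped.
#'
#' @param reads A `read_set`.
#' @param q_min Minimum terminal base quality (phred); default 20.
#' @return The trimmed `read_set`.
#' @export
trim_reads <- function(reads, q_min = 20) {
  if (nrow(reads) == 0 || q_min <= 0) return(reads)
  ## characters below q_min in phred+33: '!' .. chr(33 + q_min - 1)
  pat_pre <- paste0("^[\\x21-", sprintf("\\x%02x", 33 + q_min - 1), "]+")
  pat_suf <- paste0("[\\x21-", sprintf("\\x%02x", 33 + q_min - 1), "]+$")
  qual <- reads$quality
  lead <- attr(regexpr(pat_pre, qual, perl = TRUE), "match.length")
  lead[lead < 0] <- 0
  qual2 <- substring(qual, lead + 1)
  trail <- attr(regexpr(pat_suf, qual2, perl = TRUE), "match.length")
  trail[trail < 0] <- 0
  newlen <- nchar(qual2) - trail
  keep <- newlen > 0
  out <- reads[keep, , drop = FALSE]
  out$sequence <- substring(out$sequence, lead[keep] + 1, lead[keep] + newlen[keep])
  out$quality <- substring(qual2[keep], 1, newlen[keep])
  rownames(out) <- NULL
  class(out) <- class(reads)
  out
}

#' Hard-clip reads to a fixed length
#'
#' Keeps the first `target_length` bases (5' end); reads shorter than the
#' target are dropped. The 3' end is clipped because it is the low-quality
#' end on the sequencing platforms this pipeline emulates.
#'
#' @param reads A `read_set`.
#' @param target_length Target length in bp.
#' @return The clipped `read_set`.
#' @export
clip_reads <- function(reads, target_length = 60) {
  keep <- nchar(reads$sequence) >= target_length
  out <- reads[keep, , drop = FALSE]
  out$sequence <- substring(out$sequence, 1, target_length)
  out$quality <- substring(out$quality, 1, target_length)
  rownames(out) <- NULL
  class(out) <- class(reads)
  out
}

#' Build equalized subsample replicates across libraries
#'
#' All reads are hard-clipped to `target_length` (shorter reads dropped); the
#' smallest library (by post-clip read count) sets the per-library target
#' count. For each replicate every larger library is subsampled without
#' replacement down to that count while the smallest library passes through
#' intact. Subsampling is deterministic per (seed, replicate index).
#'
#' @param libraries Named list of `read_set` objects.
#' @param target_length Clip length in bp (default 60).
#' @param n_replicates Number of replicates (default 49).
#' @param seed Integer seed.
#' @return List of replicates; each is a named list of `read_set` objects
#'   with attributes `replicate_index`, `target_read_count` and
#'   `target_read_length`.
#' @export
equalize_libraries <- function(libraries, target_length = 60,
                               n_replicates = 49, seed = 1) {
  if (n_replicates < 1) stop_validation("n_replicates must be >= 1")
  if (length(libraries) < 1) stop_validation("no libraries given")
  clipped <- lapply(libraries, clip_reads, target_length = target_length)
  counts <- vapply(clipped, nrow, 0L)
  if (any(counts == 0)) stop_validation("a library has no reads after clipping")
  target <- min(counts)
  lapply(seq_len(n_replicates), function(r) {
    set.seed(derive_seed(seed, r))
    rep_libs <- lapply(clipped, function(lib) {
      if (nrow(lib) == target) return(lib)
      out <- lib[sort(sample.int(nrow(lib), target)), , drop = FALSE]
      rownames(out) <- NULL
      class(out) <- class(lib)
      out
    })
    attr(rep_libs, "replicate_index") <- r
    attr(rep_libs, "target_read_count") <- target
    attr(rep_libs, "target_read_length") <- target_length
    rep_libs
  })
}
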