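# Paired-end read simulation from a (synthetic) genome: uniform fragment
# starts, Gaussian insert sizes, i.i.d. base errors, positional phred model.

#' Describe a sequencing library to simulate
#'
#' @param read_length Read length in bp (the study design uses 60 or 80).
#' @param mean_depth Fold-coverage of single-copy sequence (UCOS-scale depth).
#' @param base_error_rate Per-base substitution error probability.
#' @param insert_size_mean,insert_size_sd Fragment length distribution (bp).
#' @param quality_model Function `length -> integer phred vector`; default is
#'   constant Q35 with a linear decay over the final 8 bases down to Q14,
#'   which exercises the Q20 end-trimming rule downstream.
#' @param library_id Library label.
#' @param seed Integer seed for the simulation.
#' @return A `library_profile` list.
#' @export
library_profile <- function(read_length = 60, mean_depth = 5,
                            base_error_rate = 0.01, insert_size_mean = 300,
                            insert_size_sd = 30,
                            quality_model = default_quality_model,
                            library_id = "lib1", seed = 1) {
  if (mean_depth <= 0) stop_validation("mean_depth must be > 0")
  if (read_length < 20) stop_validation("read_length too short")
  if (insert_size_mean < read_length)
    stop_validation("insert_size_mean shorter than read_length")
  if (base_error_rate < 0 || base_error_rate > 0.5)
    stop_validation("base_error_rate out of range")
  structure(list(read_length = as.integer(read_length), mean_depth = mean_depth,
                 base_error_rate = base_error_rate,
                 insert_size_mean = insert_size_mean,
                 insert_size_sd = insert_size_sd,
                 quality_model = quality_model,
                 library_id = library_id, seed = as.integer(seed)),
            class = "library_profile")
}

#' Default positional quality model
#'
#' Constant Q35 with a linear decay over the last 8 cycles down to Q14,
#' mimicking end-of-read quality loss on early Illumina machines.
#'
#' @param length Read length.
#' @return Integer phred vector.
#' @export
default_quality_model <- function(length) {
  q <- rep(35L, length)
  tail_len <- min(8L, length)
  if (tail_len > 1) {
    decay <- seq(35L, 14L, length.out = tail_len)
    q[(length - tail_len + 1):length] <- as.integer(round(decay))
  }
  q
}

#' Simulate paired-end reads from a genome
#'
#' Fragment start positions are uniform over the genome; insert sizes are
#' Gaussian (clamped to at least the read length); the forward mate reads the
#' fragment 5' end and the reverse mate the reverse complement of the 3' end.
#' Errors are injected i.i.d. at `base_error_rate`. The number of pairs is
#' `round(mean_depth * genome_size / (2 * read_length))` (round half to
#' even, R's `round`). Deterministic for a fixed profile seed.
#'
#' @param genome Genome sequence (character) or a `synthetic_reference`.
#' @param profile A [library_profile()].
#' @return A `read_set` with a `read_truth` attribute giving each read's true
#'   0-based source interval and strand.
#' @export
simulate_reads <- function(genome, profile) {
  if (inherits(genome, "synthetic_reference")) genome <- genome$genome
  G <- nchar(genome)
  rl <- profile$read_length
  if (G < profile$insert_size_mean)
    stop_validation("genome shorter than insert_size_mean")
  set.seed(profile$seed)
  n_pairs <- round(profile$mean_depth * G / (2 * rl))
  if (n_pairs < 1) stop_validation("depth too low: zero read pairs")

  ins <- pmax(rl, pmin(G, round(rnorm(n_pairs, profile$insert_size_mean,
                                      profile$insert_size_sd))))
  frag_start <- floor(runif(n_pairs, 0, G - ins + 1)) # 0-based
  fwd <- substring(genome, frag_start + 1, frag_start + rl)
  rev_start <- frag_start + ins - rl
  rev <- revcomp(substring(genome, rev_start + 1, rev_start + rl))

  seqs <- c(fwd, rev)
  err <- cpp_inject_errors(seqs, profile$base_error_rate)
  qual <- phred_to_chars(profile$quality_model(rl))
  ids <- c(sprintf("%s_p%07d/1", profile$library_id, seq_len(n_pairs)),
           sprintf("%s_p%07d/2", profile$library_id, seq_len(n_pairs)))
  reads <- read_set(read_id = ids, sequence = err$sequence,
                    quality = rep(qual, 2 * n_pairs),
                    mate = rep(c(1L, 2L), each = n_pairs),
                    library_id = profile$library_id)
  attr(reads, "read_truth") <- data.frame(
    read_id = ids,
    start = c(frag_start, rev_start),
    end = c(frag_start + rl, rev_start + rl),
    strand = rep(c("+", "-"), each = n_pairs),
    n_errors = err$n_errors,
    stringsAsFactors = FALSE
  )
  reads
}
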