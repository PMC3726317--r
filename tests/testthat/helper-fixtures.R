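# Shared fixture builders: small synthetic references, reads and pileups
# assembled in code at test time.

## three-family reference (class I / class II / satellite) on a small genome
tiny_reference <- function(seed = 42, background_length = 3e5,
                           gypsy_div = 0.03, hat_div = 0.005,
                           sat_copies = 10) {
  specs <- list(
    family_spec("gypsy1", "I", "LTR/Gypsy", 5000, 20, gypsy_div),
    family_spec("hat1", "II", "DNA/hAT", 3000, 5, hat_div),
    family_spec("sat1", "satellite", "Satellite", 2000, sat_copies, 0.01)
  )
  build_reference(specs, n_ucos = 10, ucos_length = 800,
                  background_length = background_length, seed = seed)
}

ref_contigs <- function(ref) {
  fam <- ref$truth$families
  reference_contigs(
    c(ref$te_consensus, ref$ucos),
    category = c(rep("TE", length(ref$te_consensus)),
                 rep("UCOS", length(ref$ucos))),
    te_class = c(fam$te_class, rep(NA, length(ref$ucos))),
    superfamily = c(fam$superfamily, rep(NA, length(ref$ucos)))
  )
}

sim_trimmed_reads <- function(ref, depth = 6, seed = 7, error = 0.01,
                              read_length = 60) {
  prof <- library_profile(read_length = read_length, mean_depth = depth,
                          base_error_rate = error, seed = seed)
  trim_reads(simulate_reads(ref, prof))
}

## hand-built pileup over explicit count matrices (contig sequences supplied)
manual_pileup <- function(counts_list, sequences, min_base_quality = 20) {
  contigs <- reference_contigs(sequences, category = "TE",
                               superfamily = "LTR/Gypsy")
  cols <- lapply(names(sequences), function(nm) {
    m <- counts_list[[nm]]
    rownames(m) <- c("A", "C", "G", "T")
    list(coverage = colSums(m), counts = m)
  })
  names(cols) <- names(sequences)
  structure(list(columns = cols, contigs = contigs,
                 min_base_quality = min_base_quality),
            class = "pileup")
}

## count matrix with a single specified base at every position
uniform_counts <- function(sequence, depth) {
  L <- nchar(sequence)
  m <- matrix(0L, 4, L)
  base <- match(strsplit(sequence, "")[[1]], c("A", "C", "G", "T"))
  m[cbind(base, seq_len(L))] <- depth
  m
}
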