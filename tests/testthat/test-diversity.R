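test_that("variable-site thresholds match the stated rules exactly", {
  ## contig of A's; construct tallies around each threshold
  L <- 6
  seqs <- c(c1 = strrep("A", L))
  m <- matrix(0L, 4, L)
  ## pos 1: depth 6 with strong alt -> below the depth rule ("higher than 6")
  m[1, 1] <- 3L; m[2, 1] <- 3L
  ## pos 2: depth 7, alt 3/7 -> callable
  m[1, 2] <- 4L; m[2, 2] <- 3L
  ## pos 3: depth 10 all reference -> not variable
  m[1, 3] <- 10L
  ## pos 4: alt support 1 -> below min_alt_support
  m[1, 4] <- 9L; m[3, 4] <- 1L
  ## pos 5: alt fraction 0.19 < 0.2
  m[1, 5] <- 17L; m[4, 5] <- 4L
  ## pos 6: alt fraction exactly 0.2 -> callable
  m[1, 6] <- 8L; m[4, 6] <- 2L
  pu <- manual_pileup(list(c1 = m), seqs)
  v <- call_variant_sites(pu)
  expect_equal(v$pos, c(1L, 5L))
  expect_equal(v$alt_base, c("C", "T"))
  ## depth 6 becomes callable when the threshold is lowered to 6
  v6 <- call_variant_sites(pu, min_depth = 6)
  expect_true(0L %in% v6$pos)
})

test_that("calling on a mapped pileup equals an independent tally oracle", {
  ## one family, copies tiled by deterministic reads: build alignments from
  ## truth, then compare call_variant_sites against a plain-R tally
  set.seed(41)
  cons <- random_dna(1500)
  copies <- lapply(1:8, function(i) mutate_sequence(cons, 0.05)$sequence)
  step <- 10; rl <- 60
  reads <- character(0); starts <- integer(0)
  for (cp in copies) {
    s <- seq(1, nchar(cp) - rl + 1, by = step)
    reads <- c(reads, substring(cp, s, s + rl - 1))
    starts <- c(starts, s - 1L)
  }
  rs <- read_set(sprintf("r%d", seq_along(reads)), reads,
                 rep(strrep("I", rl), length(reads)))
  contigs <- reference_contigs(c(fam = cons), superfamily = "LTR/Gypsy")
  aln <- data.frame(read = seq_along(reads), read_id = rs$read_id,
                    contig_id = "fam", contig = 1L, start = starts,
                    strand = "+", aligned_length = rl, mismatches = 0L,
                    mapq = 37L)
  pu <- pileup(aln, rs, contigs)
  v <- call_variant_sites(pu)
  ## oracle: tally characters position by position in plain R
  refc <- strsplit(cons, "")[[1]]
  tall <- matrix(0L, 4, nchar(cons))
  for (i in seq_along(reads)) {
    ch <- strsplit(reads[i], "")[[1]]
    for (j in seq_len(rl)) {
      b <- match(ch[j], c("A", "C", "G", "T"))
      tall[b, starts[i] + j] <- tall[b, starts[i] + j] + 1L
    }
  }
  depth <- colSums(tall)
  alt <- tall
  alt[cbind(match(refc, c("A", "C", "G", "T")), seq_along(refc))] <- 0L
  best <- apply(alt, 2, max)
  oracle <- which(depth >= 7 & best >= 2 & best / depth >= 0.2) - 1L
  expect_equal(v$pos, oracle)
})

test_that("diversity is variable sites over contig length with a log floor", {
  contigs <- reference_contigs(c(a = strrep("A", 1000), b = strrep("A", 500)),
                               superfamily = "LTR/Gypsy", te_class = "I")
  v <- data.frame(contig_id = rep("a", 10), pos = 0:9)
  d <- nucleotide_diversity(v, contigs)
  expect_equal(d$diversity, c(0.01, 0))
  expect_equal(d$log10_diversity[2], log10(1 / 1000)) # floor 1/(2*500)
  s <- diversity_summary(d)
  expect_equal(s$median_diversity, 0.005)
})

test_that("variant partitioning conserves counts and lengths", {
  ann <- data.frame(contig_id = "el",
                    feature = c("LTR", "RT", "LTR"),
                    start = c(0L, 400L, 900L), end = c(100L, 500L, 1000L))
  contigs <- reference_contigs(c(el = strrep("A", 1000)),
                               superfamily = "LTR/Gypsy")
  ## all variants inside LTRs
  v <- data.frame(contig_id = "el", pos = c(5L, 50L, 950L))
  p <- partition_variants(v, ann, contigs)
  expect_equal(p$percent_of_total[p$feature == "LTR"], 100)
  expect_equal(sum(p$percent_of_total), 100)
  expect_equal(sum(p$total_feature_length), 1000)
  ## constructed 90/5/5 split outside/LTR/genes
  v2 <- data.frame(
    contig_id = "el",
    pos = c(sample(100:399, 45), sample(500:899, 45),  # outside: 90
            sample(0:99, 5),                           # LTR: 5
            sample(400:499, 5)))                       # RT: 5
  p2 <- partition_variants(v2, ann, contigs)
  expect_equal(p2$percent_of_total[p2$feature == "outside"], 90)
  expect_equal(p2$percent_of_total[p2$feature == "LTR"], 5)
  expect_equal(p2$percent_of_total[p2$feature == "RT"], 5)
  expect_equal(attr(p2, "total_variants"), 100)
  expect_equal(p2$per_bp_rate, p2$variant_count / p2$total_feature_length)
  ## gene precedence beats LTR on overlap
  ann3 <- data.frame(contig_id = "el", feature = c("LTR", "RT"),
                     start = c(0L, 50L), end = c(100L, 100L))
  p3 <- partition_variants(data.frame(contig_id = "el", pos = 60L), ann3,
                           contigs)
  expect_equal(p3$variant_count[p3$feature == "RT"], 1L)
  ## strict mode rejects unannotated contigs
  expect_error(partition_variants(data.frame(contig_id = "zz", pos = 1L),
                                  ann, contigs, strict = TRUE),
               class = "teshot_validation_error")
})

test_that("GFF3 annotations round-trip through the LTRdigest dialect", {
  ann <- data.frame(contig_id = c("el", "el", "el"),
                    feature = c("LTR", "RT", "LTR"),
                    start = c(0L, 400L, 900L), end = c(100L, 500L, 1000L),
                    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".gff3")
  write_feature_gff3(ann, f)
  back <- read_feature_gff3(f)
  expect_equal(back, ann)
  ## LTRdigest-style container and RR_tract records are ignored
  writeLines(c("##gff-version 3",
               "el\tLTRdigest\tLTR_retrotransposon\t1\t1000\t.\t+\t.\tID=x",
               "el\tLTRdigest\tRR_tract\t850\t870\t.\t+\t.\tID=y",
               "el\tLTRdigest\tlong_terminal_repeat\t1\t100\t.\t+\t.\tID=z",
               "el\tLTRdigest\tprotein_match\t401\t500\t.\t+\t.\tName=RT"), f)
  back2 <- read_feature_gff3(f)
  expect_equal(back2$feature, c("LTR", "RT"))
  expect_equal(back2$start, c(0L, 400L))
})

test_that("higher per-copy divergence raises called diversity until mapping truncates it", {
  base_div <- function(div, seed) {
    specs <- list(family_spec("fam", "I", "LTR/Gypsy", 3000, 5, div))
    ref <- build_reference(specs, n_ucos = 4, ucos_length = 600,
                           background_length = 5e4, seed = seed)
    reads <- sim_trimmed_reads(ref, depth = 7, seed = seed + 1)
    contigs <- ref_contigs(ref)
    set.seed(seed)
    aln <- map_reads(reads, build_index(contigs))
    v <- call_variant_sites(pileup(aln, reads, contigs), contig_ids = "fam")
    nrow(v) / 3000
  }
  d <- vapply(c(0.005, 0.05, 0.30), base_div, 0, seed = 61)
  expect_lt(d[1], d[2])   # more divergence, more called sites...
  expect_lt(d[3], d[2])   # ...until reads stop mapping (mismatch ceiling)
})
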