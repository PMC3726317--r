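test_that("family_spec validates its inputs", {
  expect_error(family_spec("f", "I", "LTR/Gypsy", 1000, -1),
               class = "teshot_validation_error")
  expect_error(family_spec("f", "I", "LTR/Gypsy", 1000, 5, 0.6),
               class = "teshot_validation_error")
  fs <- family_spec("f", "I", "LTR/Gypsy", 1000, 5, 0.05)
  ltr <- fs$feature_layout[fs$feature_layout$feature == "LTR", ]
  expect_equal(nrow(ltr), 2)
  expect_equal(diff(ltr$end - ltr$start), 0) # equal-length LTRs
  ## features disjoint and within the consensus
  fl <- fs$feature_layout[order(fs$feature_layout$start), ]
  expect_true(all(fl$start >= 0 & fl$end <= 1000))
  expect_true(all(fl$start[-1] >= fl$end[-nrow(fl)]))
})

test_that("build_reference rejects invalid requests", {
  s <- family_spec("f", "I", "LTR/Gypsy", 5000, 100)
  expect_error(build_reference(list(s), background_length = 1e4, seed = 1),
               class = "teshot_validation_error")
  s2 <- family_spec("f", "II", "DNA/hAT", 1000, 1)
  expect_error(build_reference(list(s, s2)[c(1, 1)], background_length = 1e6),
               class = "teshot_validation_error") # duplicate family_id
})

test_that("zero copies and zero divergence behave exactly", {
  specs <- list(family_spec("none", "I", "LTR/Gypsy", 2000, 0),
                family_spec("exact", "II", "DNA/hAT", 1500, 5, 0))
  ref <- build_reference(specs, n_ucos = 2, ucos_length = 500,
                         background_length = 5e4, seed = 3)
  expect_named(ref$te_consensus, c("none", "exact"))
  expect_equal(sum(ref$truth$placements$family_id == "none"), 0)
  expect_equal(ref$truth$families$copy_number[1], 0L)
  ## 5 exact (possibly reverse-complemented) copies present in the genome
  pl <- ref$truth$placements[ref$truth$placements$family_id == "exact", ]
  expect_equal(nrow(pl), 5)
  for (i in seq_len(5)) {
    emitted <- substr(ref$genome, pl$start[i] + 1, pl$end[i])
    if (pl$strand[i] == "-") emitted <- revcomp(emitted)
    expect_identical(emitted, unname(ref$te_consensus["exact"]))
  }
})

test_that("per-copy divergence is binomial around the requested rate", {
  spec <- family_spec("div", "I", "LTR/Gypsy", 5000, 20, 0.05)
  ref <- build_reference(list(spec), n_ucos = 0, ucos_length = 100,
                         background_length = 2e5, seed = 11)
  pl <- ref$truth$placements
  cons <- strsplit(ref$te_consensus[["div"]], "")[[1]]
  mism <- vapply(seq_len(nrow(pl)), function(i) {
    emitted <- substr(ref$genome, pl$start[i] + 1, pl$end[i])
    if (pl$strand[i] == "-") emitted <- revcomp(emitted)
    mean(strsplit(emitted, "")[[1]] != cons)
  }, 0)
  ## binomial 3-sigma bound on the mean over 20 x 5000 sites
  expect_gt(mean(mism), 0.04)
  expect_lt(mean(mism), 0.06)
  expect_equal(vapply(seq_len(nrow(pl)), function(i) {
    emitted <- substr(ref$genome, pl$start[i] + 1, pl$end[i])
    if (pl$strand[i] == "-") emitted <- revcomp(emitted)
    sum(strsplit(emitted, "")[[1]] != cons)
  }, 0), as.numeric(pl$n_mut))
})

test_that("truth records every placement inside the genome", {
  ref <- tiny_reference(seed = 5)
  tr <- ref$truth
  expect_equal(tr$genome_size, nchar(ref$genome))
  expect_true(all(tr$placements$start >= 0))
  expect_true(all(tr$placements$end <= tr$genome_size))
  ## occupancy equals copy_number * consensus_length / genome_size
  occ <- with(tr$placements[tr$placements$type == "TE", ],
              tapply(end - start, family_id, sum))
  expected <- with(tr$families,
                   setNames(as.numeric(copy_number) * consensus_length,
                            family_id))
  expect_equal(occ[names(expected)], expected[names(expected)],
               ignore_attr = TRUE)
  ## UCOS genes appear exactly once
  expect_equal(nrow(tr$ucos), 10)
})

test_that("simulated pair count follows the coverage arithmetic", {
  g <- random_dna(1e5)
  prof <- library_profile(read_length = 60, mean_depth = 10, seed = 1)
  reads <- simulate_reads(g, prof)
  expect_equal(nrow(reads), 2 * round(10 * 1e5 / (2 * 60))) # 8333 pairs
  expect_error(library_profile(read_length = 60, insert_size_mean = 50),
               class = "teshot_validation_error")
})

test_that("error-free reads are exact substrings at their truth coordinates", {
  set.seed(2)
  g <- random_dna(5e4)
  prof <- library_profile(read_length = 60, mean_depth = 3,
                          base_error_rate = 0, seed = 4)
  reads <- simulate_reads(g, prof)
  rt <- attr(reads, "read_truth")
  src <- substring(g, rt$start + 1, rt$end)
  src[rt$strand == "-"] <- revcomp(src[rt$strand == "-"])
  expect_identical(reads$sequence, src)
})

test_that("injected error rate matches the requested rate", {
  set.seed(2)
  g <- random_dna(2e5)
  prof <- library_profile(read_length = 60, mean_depth = 3,
                          base_error_rate = 0.01, seed = 9)
  reads <- simulate_reads(g, prof)
  rt <- attr(reads, "read_truth")
  src <- substring(g, rt$start + 1, rt$end)
  src[rt$strand == "-"] <- revcomp(src[rt$strand == "-"])
  mism <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                 reads$sequence[1:5000], src[1:5000])
  rate <- sum(mism) / (5000 * 60)
  expect_gt(rate, 0.008)
  expect_lt(rate, 0.012)
})

test_that("fixed seeds give byte-identical FASTA/FASTQ outputs", {
  ref1 <- tiny_reference(seed = 8, background_length = 2e5, sat_copies = 2)
  ref2 <- tiny_reference(seed = 8, background_length = 2e5, sat_copies = 2)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(c(genome = ref1$genome), f1)
  write_fasta(c(genome = ref2$genome), f2)
  expect_identical(readLines(f1), readLines(f2))
  r1 <- simulate_reads(ref1, library_profile(mean_depth = 2, seed = 5))
  r2 <- simulate_reads(ref2, library_profile(mean_depth = 2, seed = 5))
  q1 <- tempfile(); q2 <- tempfile()
  write_fastq(r1, q1); write_fastq(r2, q2)
  expect_identical(readLines(q1), readLines(q2))
})

test_that("truth files round-trip exactly and idempotently", {
  ref <- tiny_reference(seed = 13, background_length = 2e5, sat_copies = 3)
  f <- tempfile()
  write_truth(ref$truth, f)
  back <- read_truth(f)
  expect_equal(unclass(back), unclass(ref$truth), ignore_attr = TRUE)
  f2 <- tempfile()
  write_truth(back, f2)
  expect_identical(readLines(f), readLines(f2))
  ## one family, 3 copies -> 3 TE placement rows
  one <- build_reference(list(family_spec("x", "II", "DNA/hAT", 1000, 3)),
                         n_ucos = 0, ucos_length = 100,
                         background_length = 2e4, seed = 1)
  f3 <- tempfile()
  write_truth(one$truth, f3)
  expect_equal(sum(read_truth(f3)$placements$type == "TE"), 3)
})
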