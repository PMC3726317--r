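test_that("the seed index records every k-mer occurrence on both strands", {
  contigs <- reference_contigs(c(c1 = "ACGTACGTACGT"), category = "other")
  idx <- build_index(contigs, k = 8)
  hits <- index_lookup(idx, "ACGTACGT")
  fwd <- hits[hits$strand == "+", ]
  expect_setequal(fwd$pos, c(0, 4))
  ## ACGTACGT is its own reverse complement: one - hit per strand occurrence
  expect_equal(sum(hits$strand == "-"), 2)
  expect_equal(nrow(index_lookup(idx, "AAAAAAAA")), 0)
  expect_error(build_index(contigs, k = 4), class = "teshot_validation_error")
})

test_that("reads map back to their exact origin on either strand", {
  set.seed(21)
  seqs <- c(c1 = random_dna(2000), c2 = random_dna(1500))
  contigs <- reference_contigs(seqs, category = "other")
  idx <- build_index(contigs, k = 13)
  read <- substr(seqs["c2"], 301, 360)
  set.seed(1)
  aln <- map_reads(c(r = read), idx)
  expect_equal(aln$contig_id, "c2")
  expect_equal(aln$start, 300)
  expect_equal(aln$strand, "+")
  expect_equal(aln$mismatches, 0)
  expect_equal(aln$mapq, 37L)
  aln_rc <- map_reads(c(r = revcomp(read)), idx)
  expect_equal(aln_rc$start, 300)
  expect_equal(aln_rc$strand, "-")
  ## a read with no home stays unmapped
  none <- map_reads(c(r = strrep("ACGT", 15)), idx)
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "n_unmapped"), 1)
})

test_that("ties between identical loci are broken uniformly at random", {
  set.seed(77)
  block <- random_dna(400)
  contigs <- reference_contigs(c(a = block, b = block), category = "other")
  idx <- build_index(contigs, k = 13)
  read <- substr(block, 101, 160)
  set.seed(5)
  aln <- map_reads(rep(read, 10000), idx)
  expect_equal(nrow(aln), 10000)
  expect_true(all(aln$mapq == 0L))
  frac_a <- mean(aln$contig_id == "a")
  expect_gt(frac_a, 0.48)
  expect_lt(frac_a, 0.52)
})

test_that("the seeded mapper agrees with the exhaustive aligner on best mismatch count", {
  set.seed(55)
  seqs <- c(c1 = random_dna(1200), c2 = random_dna(800))
  contigs <- reference_contigs(seqs, category = "other")
  idx <- build_index(contigs, k = 13)
  ## 1000 reads: clean, mutated and reverse-complemented draws
  reads <- character(1000)
  for (i in 1:1000) {
    src <- if (i %% 2) seqs["c1"] else seqs["c2"]
    s <- sample.int(nchar(src) - 60, 1)
    r <- substr(src, s + 1, s + 60)
    r <- mutate_sequence(r, sample(c(0, 0.02, 0.05), 1))$sequence
    if (i %% 3 == 0) r <- revcomp(r)
    reads[i] <- r
  }
  set.seed(2)
  aln <- map_reads(reads, idx, max_mismatch_rate = 0.1)
  oracle <- cpp_brute_best_mismatch(reads, unname(seqs))
  expect_equal(aln$mismatches, oracle[aln$read])
  ## seeding can miss a placement only when every seed overlaps a mutation,
  ## so recall against the exhaustive aligner stays high
  mappable <- which(oracle <= ceiling(0.1 * 60))
  expect_true(all(aln$read %in% mappable))
  expect_gt(length(intersect(aln$read, mappable)) / length(mappable), 0.95)
  ## clean reads are never missed
  clean <- intersect(which(oracle == 0), seq_along(reads))
  expect_true(all(clean %in% aln$read))
})

test_that("pileup coverage sums to the aligned base count", {
  ref <- tiny_reference(seed = 17, background_length = 2e5, sat_copies = 2)
  reads <- sim_trimmed_reads(ref, depth = 3, seed = 3)
  contigs <- ref_contigs(ref)
  idx <- build_index(contigs)
  set.seed(4)
  aln <- map_reads(reads, idx)
  pu <- pileup(aln, reads, contigs)
  total_cov <- sum(vapply(pu$columns, function(x) sum(x$coverage), 0))
  expect_equal(total_cov, sum(aln$aligned_length))
  ## no alignments -> all-zero arrays of the right lengths
  empty <- pileup(aln[0, ], reads, contigs)
  expect_equal(vapply(empty$columns, function(x) sum(x$coverage), 0),
               setNames(rep(0, nrow(contigs)), contigs$contig_id))
  expect_equal(vapply(empty$columns, function(x) length(x$coverage), 0L),
               setNames(nchar(contigs$sequence), contigs$contig_id))
})

test_that("two overlapping reads give depth two and correct allele tallies", {
  contigs <- reference_contigs(c(c1 = strrep("A", 100)), category = "other")
  reads <- read_set(c("r1", "r2"),
                    c(strrep("A", 60), strrep("A", 60)),
                    c(strrep("I", 60), strrep("I", 60)))
  aln <- data.frame(read = 1:2, read_id = c("r1", "r2"), contig_id = "c1",
                    contig = 1L, start = c(0L, 20L), strand = "+",
                    aligned_length = 60L, mismatches = 0L, mapq = 37L)
  pu <- pileup(aln, reads, contigs)
  expect_equal(pu$columns$c1$coverage[21:60], rep(2L, 40))
  expect_equal(unname(pu$columns$c1$counts["A", 21]), 2L)
  expect_equal(sum(pu$columns$c1$counts[c("C", "G", "T"), ]), 0L)
})

test_that("SAM records round-trip with the coordinate conventions intact", {
  set.seed(13)
  seqs <- c(c1 = random_dna(500))
  contigs <- reference_contigs(seqs, category = "other")
  idx <- build_index(contigs, k = 13)
  reads <- read_set(
    c("a", "b"),
    c(substr(seqs, 101, 160), revcomp(substr(seqs, 201, 260))),
    c(strrep("I", 60), strrep("I", 60)))
  set.seed(1)
  aln <- map_reads(reads, idx)
  f <- tempfile(fileext = ".sam")
  export_sam(aln, reads, contigs, f)
  back <- import_sam(f, contigs)
  expect_equal(back$start, aln$start)
  expect_equal(back$strand, aln$strand)
  expect_equal(back$mismatches, aln$mismatches)
  ## POS is 1-based in the file, 0-based in memory
  pos_field <- as.integer(vapply(strsplit(grep("^[ab]\t", readLines(f),
                                               value = TRUE), "\t"),
                                 `[`, "", 4))
  expect_equal(sort(pos_field), sort(aln$start + 1L))
  ## unmapped FLAG 4 records are skipped and counted
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:c1\tLN:500",
               "u\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\tIIII",
               sprintf("m\t0\tc1\t101\t37\t60M\t*\t0\t0\t%s\t%s\tNM:i:0",
                       substr(seqs, 101, 160), strrep("I", 60))), f)
  imp <- import_sam(f, contigs)
  expect_equal(nrow(imp), 1)
  expect_equal(imp$start, 100L)
  expect_equal(attr(imp, "n_skipped_unmapped"), 1L)
  ## unknown reference names are rejected
  writeLines(c("@SQ\tSN:zzz\tLN:10"), f)
  expect_error(import_sam(f, contigs), class = "teshot_validation_error")
})

test_that("error-free simulations map completely at the expected coverage", {
  specs <- list(family_spec("f1", "II", "DNA/hAT", 2000, 4, 0))
  ref <- build_reference(specs, n_ucos = 4, ucos_length = 600,
                         background_length = 5e4, seed = 23)
  prof <- library_profile(mean_depth = 5, base_error_rate = 0, seed = 6)
  reads <- simulate_reads(ref, prof)
  contigs <- ref_contigs(ref)
  idx <- build_index(contigs)
  set.seed(3)
  aln <- map_reads(reads, idx)
  ## reads overlapping an element interior by >= 80% should essentially all map;
  ## here check total mapped fraction against truth-derived expectation
  rt <- attr(reads, "read_truth")
  lab <- read_truth_labels(ref, rt)
  interior <- lab != "bg"
  expect_gt(nrow(aln) / sum(interior), 0.85)
  pu <- pileup(aln, reads, contigs)
  cm <- mean(pu$columns$f1$coverage)
  expect_gt(cm, 4 * 5 * 0.8)
  expect_lt(cm, 4 * 5 * 1.2)
})
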