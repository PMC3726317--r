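test_that("consensus calling applies depth and majority rules", {
  L <- 5
  m <- matrix(0L, 4, L)
  m[1, 1] <- 5L                 # depth 5 -> N ("6 or more" required)
  m[1, 2] <- 6L                 # depth 6 -> called
  m[1, 3] <- 10L                # unanimous -> A
  m[1, 4] <- 7L; m[2, 4] <- 3L  # 0.7 < 0.8 -> N (heterozygote)
  m[1, 5] <- 8L; m[2, 5] <- 2L  # 0.8 -> called A
  pu <- manual_pileup(list(u1 = m), c(u1 = strrep("G", L)))
  cs <- consensus_sequences(pu)
  expect_equal(unname(cs["u1"]), "NAANA")
})

test_that("column and locus filtering follows the nogap and length-50 rules", {
  mk <- function(len, with_n = FALSE) {
    s <- strrep("A", len)
    out <- c(x = s, y = s, z = s)
    if (with_n) substr(out["y"], 3, 3) <- "N"
    out
  }
  loci <- list(l49 = mk(49), l50 = mk(50), l51n = mk(51, with_n = TRUE))
  lm <- filter_columns_and_loci(loci)
  expect_setequal(names(lm$loci), c("l50", "l51n"))  # 49 dropped, 50 kept
  expect_equal(nchar(lm$loci$l51n[["x"]]), 50)       # one N column removed
  expect_equal(lm$dropped, "l49")
  expect_equal(nchar(lm$concatenated[["x"]]), 100)
  expect_equal(lm$partition$end, c(50L, 100L))
  ## no Ns anywhere: matrix length is the sum of locus lengths
  lm2 <- filter_columns_and_loci(list(a = mk(60), b = mk(70)))
  expect_equal(nchar(lm2$concatenated[["x"]]), 130)
  ## NEXUS output parses back to the same matrix
  f <- tempfile(fileext = ".nex")
  write_nexus_matrix(lm, f)
  nex <- ape::read.nexus.data(f)
  expect_equal(toupper(paste(nex$x, collapse = "")), lm$concatenated[["x"]])
  expect_true(any(grepl("CHARSET l50 = 1-50", readLines(f))))
})

test_that("NJ recovers additive trees exactly and flags saturation", {
  tru <- ape::read.tree(text = "((A:1,B:2):1.5,(C:0.7,D:1.2):0.8);")
  d <- ape::cophenetic.phylo(tru)
  rec <- ape::nj(as.dist(d))
  expect_equal(ape::dist.topo(ape::unroot(tru), ape::unroot(rec)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(ape::cophenetic.phylo(rec)[rownames(d), colnames(d)]),
               sort(d), tolerance = 1e-10)
  ## identical sequences -> star tree with zero branch lengths
  s <- strrep("ACGT", 30)
  tr <- nj_gene_tree(c(a = s, b = s, c = s))
  expect_equal(tr$Nnode, 1)
  expect_equal(unname(tr$edge.length), rep(0, 3))
  expect_error(nj_gene_tree(c(a = s, b = s)),
               class = "teshot_validation_error")
  expect_error(nj_gene_tree(c(a = strrep("A", 100), b = strrep("C", 100),
                              c = strrep("G", 100))),
               class = "teshot_validation_error") # saturated
})

test_that("gene trees estimated from sequences match the generating topology", {
  set.seed(3)
  anc <- random_dna(400)
  ab <- mutate_sequence(anc, 0.02)$sequence
  cd <- mutate_sequence(anc, 0.02)$sequence
  seqs <- c(A = mutate_sequence(ab, 0.01)$sequence,
            B = mutate_sequence(ab, 0.01)$sequence,
            C = mutate_sequence(cd, 0.01)$sequence,
            D = mutate_sequence(cd, 0.01)$sequence)
  tr <- nj_gene_tree(seqs)
  expect_true(teshot:::is_monophyletic_unrooted(tr, c("A", "B")))
})

test_that("STAR rank distances match the hand-computed convention", {
  gt <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  st <- star_species_tree(list(gt, gt), outgroup = "C")
  d <- attr(st, "rank_distance")
  expect_equal(d["A", "B"], 4)
  expect_equal(d["A", "C"], 6)
  expect_equal(d["B", "C"], 6)
  expect_true(teshot:::is_monophyletic_unrooted(st, c("A", "B")))
  ## a single gene tree returns its own topology
  gt5 <- ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,O:3);")
  st5 <- star_species_tree(gt5, outgroup = "O")
  expect_equal(ape::dist.topo(ape::unroot(st5), ape::unroot(gt5)), 0,
               ignore_attr = TRUE)
  ## missing outgroup: skipped with warning; none usable is an error
  noout <- ape::read.tree(text = "((A:1,B:1):1,D:2);")
  expect_warning(star_species_tree(list(gt5, noout), "O"), "outgroup")
  expect_error(suppressWarnings(star_species_tree(list(noout), "O")),
               class = "teshot_validation_error")
})

test_that("STAR returns the common topology of concordant gene trees (exhaustive, 5 taxa)", {
  skip_if_not_installed("phangorn")
  all5 <- phangorn::allTrees(5, rooted = FALSE, tip.label = c("O", "A", "B", "C", "D"))
  for (i in seq_along(all5)) {
    topo <- all5[[i]] # [[ restores tip labels from the compressed multiPhylo
    topo$edge.length <- rep(1, nrow(topo$edge))
    st <- star_species_tree(list(topo, topo, topo), outgroup = "O")
    expect_equal(ape::dist.topo(ape::unroot(st), ape::unroot(topo)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("multilocus bootstrap gives full support to unanimous signal", {
  gt <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,O:3);")
  loci <- setNames(rep(list(gt), 6), paste0("l", 1:6))
  bs <- multilocus_bootstrap(loci, outgroup = "O", B = 25, seed = 2)
  expect_equal(clade_support(bs, c("A", "B")), 100)
  expect_equal(ape::dist.topo(ape::unroot(bs$tree), ape::unroot(gt)), 0,
               ignore_attr = TRUE)
  expect_error(multilocus_bootstrap(loci, "O", B = 0),
               class = "teshot_validation_error")
  expect_error(multilocus_bootstrap(loci[1], "O", B = 5),
               class = "teshot_validation_error")
})
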