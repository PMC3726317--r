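# Validation experiments shared by the acceptance test suite and
# scripts/acceptance.R (which sources this file from the repository root).
# Every experiment takes a seed and returns the measured quantities; all
# study conditions (genome sizes, copy numbers, divergences, depths) are
# fixed here and documented in the methods vignette.

## deterministic child seeds (kept below 2^31)
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483629
}

## truth label of each simulated read (family id or "bg"), by read midpoint
read_truth_labels <- function(ref, read_truth) {
  pl <- ref$truth$placements
  mid <- (read_truth$start + read_truth$end) / 2
  lab <- rep("bg", nrow(read_truth))
  for (i in seq_len(nrow(pl))) {
    hit <- mid >= pl$start[i] & mid < pl$end[i]
    lab[hit] <- pl$family_id[i]
  }
  lab
}

## --- copy-number recovery -------------------------------------------------
## ~2 Mb genome: 20 UCOS genes, six TE families spanning copy numbers
## {1, 5, 20, 100} at per-copy divergences up to 5%, 6x single-copy depth.
experiment_copy_number <- function(seed) {
  specs <- list(
    family_spec("gypsyA", "I", "LTR/Gypsy", 5000, 1, 0.00),
    family_spec("copiaA", "I", "LTR/Copia", 4000, 5, 0.01),
    family_spec("hatA", "II", "DNA/hAT", 3000, 20, 0.02),
    family_spec("gypsyB", "I", "LTR/Gypsy", 5000, 100, 0.03),
    family_spec("mudrA", "II", "DNA/Mutator", 4000, 5, 0.04),
    family_spec("harbA", "II", "DNA/Harbinger", 3000, 20, 0.05)
  )
  ref <- build_reference(specs, n_ucos = 20, ucos_length = 1500,
                         background_length = 1.2e6, seed = seed)
  prof <- library_profile(read_length = 60, mean_depth = 6,
                          base_error_rate = 0.01,
                          seed = derive_seed(seed, 1))
  reads <- trim_reads(simulate_reads(ref, prof))
  fam <- ref$truth$families
  contigs <- reference_contigs(
    c(ref$te_consensus, ref$ucos),
    category = c(rep("TE", nrow(fam)), rep("UCOS", length(ref$ucos))),
    te_class = c(fam$te_class, rep(NA, length(ref$ucos))),
    superfamily = c(fam$superfamily, rep(NA, length(ref$ucos))))
  idx <- build_index(contigs)
  set.seed(derive_seed(seed, 2))
  aln <- map_reads(reads, idx)
  tab <- copy_number_table(pileup(aln, reads, contigs), "sim")
  truth_cn <- setNames(fam$copy_number, fam$family_id)
  est_cn <- setNames(tab$families$relative_copy_number, tab$families$family_id)
  rel_err <- abs(est_cn[names(truth_cn)] - truth_cn) / truth_cn
  list(ref = ref, reads = reads, contigs = contigs, table = tab,
       truth_cn = truth_cn, est_cn = est_cn[names(truth_cn)],
       rel_err = rel_err, median_rel_err = unname(median(rel_err)),
       specs = specs)
}

## --- mapping vs de novo under consensus drift -----------------------------
## The same six families drifted 25% from the mapping reference (plus 5%
## per-copy divergence); mapping-based fractions collapse while
## clustering-based fractions track the truth.
experiment_divergence_effect <- function(seed, base = NULL) {
  if (is.null(base)) base <- experiment_copy_number(seed)
  set.seed(derive_seed(seed, 3))
  drifted <- vapply(base$ref$te_consensus,
                    function(s) mutate_sequence(s, 0.25)$sequence, "")
  fam <- base$ref$truth$families
  specs2 <- lapply(seq_len(nrow(fam)), function(i) {
    family_spec(fam$family_id[i], fam$te_class[i], fam$superfamily[i],
                fam$consensus_length[i], fam$copy_number[i],
                per_copy_divergence = 0.05,
                consensus = drifted[[fam$family_id[i]]])
  })
  ref2 <- build_reference(specs2, background_length = 1.2e6,
                          seed = derive_seed(seed, 4),
                          ucos = base$ref$ucos)
  prof <- library_profile(read_length = 60, mean_depth = 6,
                          base_error_rate = 0.01,
                          seed = derive_seed(seed, 5))
  raw <- simulate_reads(ref2, prof)
  reads <- trim_reads(raw)
  ## mapping-based fractions against the ORIGINAL (undrifted) reference
  idx <- build_index(base$contigs)
  set.seed(derive_seed(seed, 6))
  aln <- map_reads(reads, idx)
  tab <- copy_number_table(pileup(aln, reads, contigs = base$contigs), "drift")
  gs2 <- ref2$truth$genome_size
  map_frac <- setNames(family_genome_fraction(tab, gs2)$fraction,
                       tab$families$family_id)
  truth_frac <- setNames(as.numeric(fam$copy_number) * fam$consensus_length /
                           gs2, fam$family_id)
  ## de novo clustering on the same reads, attributed by planted truth
  g <- build_read_graph(reads, vertex_budget = 25000,
                        seed = derive_seed(seed, 7))
  part <- louvain_clusters(g, seed = derive_seed(seed, 8))
  lab <- read_truth_labels(ref2, attr(raw, "read_truth"))[g$used]
  sizes <- table(part)
  cl_lab <- tapply(lab, part, function(x) names(which.max(table(x))))
  keep <- 100 * as.numeric(sizes) / length(lab) >= 0.01
  clu_pct <- tapply(as.numeric(sizes[keep]), cl_lab[names(sizes)[keep]], sum) /
    length(lab) * 100
  clu_frac <- setNames(rep(0, nrow(fam)), fam$family_id)
  hit <- intersect(names(clu_pct), names(clu_frac))
  clu_frac[hit] <- clu_pct[hit] / 100
  list(
    truth_frac = truth_frac,
    map_frac = map_frac[names(truth_frac)],
    clu_frac = clu_frac[names(truth_frac)],
    mapping_rel_drop = 1 - sum(map_frac) / sum(truth_frac),
    clustering_max_dev_points = 100 * max(abs(clu_frac[names(truth_frac)] -
                                                truth_frac))
  )
}

## --- class I vs class II diversity and feature partitioning ---------------
## Five class I families at 5% inter-copy divergence vs five class II at
## 0.5%, five copies each at 6x single-copy depth.
experiment_diversity <- function(seed) {
  mk <- function(i, cls, sf, div)
    family_spec(sprintf("%s%02d", gsub("[^A-Za-z]", "", sf), i), cls, sf,
                5000, 5, div)
  specs <- c(
    lapply(1:3, mk, cls = "I", sf = "LTR/Gypsy", div = 0.05),
    lapply(4:5, mk, cls = "I", sf = "LTR/Copia", div = 0.05),
    lapply(1:3, mk, cls = "II", sf = "DNA/hAT", div = 0.005),
    lapply(4:5, mk, cls = "II", sf = "DNA/Mutator", div = 0.005)
  )
  ref <- build_reference(specs, n_ucos = 10, ucos_length = 1000,
                         background_length = 4e5, seed = derive_seed(seed, 9))
  prof <- library_profile(read_length = 60, mean_depth = 6,
                          base_error_rate = 0.01,
                          seed = derive_seed(seed, 10))
  reads <- trim_reads(simulate_reads(ref, prof))
  fam <- ref$truth$families
  contigs <- reference_contigs(
    c(ref$te_consensus, ref$ucos),
    category = c(rep("TE", nrow(fam)), rep("UCOS", length(ref$ucos))),
    te_class = c(fam$te_class, rep(NA, length(ref$ucos))),
    superfamily = c(fam$superfamily, rep(NA, length(ref$ucos))))
  idx <- build_index(contigs)
  set.seed(derive_seed(seed, 11))
  aln <- map_reads(reads, idx)
  pu <- pileup(aln, reads, contigs)
  v <- call_variant_sites(pu, contig_ids = fam$family_id)
  d <- nucleotide_diversity(v, contigs[contigs$category == "TE", ])
  med <- tapply(d$diversity, d$te_class, median)
  part <- partition_variants(v[v$contig_id %in%
                                 fam$family_id[fam$te_class == "I"], ],
                             ref$features[ref$features$contig_id %in%
                                            fam$family_id[fam$te_class == "I"], ],
                             contigs[contigs$te_class %in% "I", ])
  list(diversity = d, ratio = unname(med[["I"]] / med[["II"]]),
       partition = part)
}

## z-scores of per-feature rates against the pooled rate (binomial model)
partition_rate_zscores <- function(part,
                                   features = c("LTR", "GAG", "AP", "RT",
                                                "RH", "IT")) {
  p <- part[part$feature %in% features, , drop = FALSE]
  pooled <- sum(p$variant_count) / sum(p$total_feature_length)
  (p$per_bp_rate - pooled) /
    sqrt(pooled * (1 - pooled) / p$total_feature_length)
}

## --- PCA fingerprinting with planted two-group structure ------------------
## Eight accessions sharing one reference; the second group carries twice
## the LTR/Copia and DNA/hAT copy numbers. 3x depth, 49 equalized replicates.
experiment_pca <- function(seed, n_replicates = 49) {
  set.seed(derive_seed(seed, 12))
  shared <- list(
    gypsy = list(id = "gypsy1", cls = "I", sf = "LTR/Gypsy", len = 3000,
                 seq = random_dna(3000)),
    copia = list(id = "copia1", cls = "I", sf = "LTR/Copia", len = 2500,
                 seq = random_dna(2500)),
    hat = list(id = "hat1", cls = "II", sf = "DNA/hAT", len = 2000,
               seq = random_dna(2000)),
    mudr = list(id = "mudr1", cls = "II", sf = "DNA/Mutator", len = 2000,
                seq = random_dna(2000)),
    harb = list(id = "harb1", cls = "II", sf = "DNA/Harbinger", len = 2000,
                seq = random_dna(2000))
  )
  ## a sizeable UCOS panel keeps the per-sample depth baseline tight; with
  ## too few single-copy genes the baseline error becomes a common-mode
  ## axis that can outweigh planted structure
  ucos <- setNames(vapply(1:30, function(i) random_dna(1000), ""),
                   sprintf("ucos_%02d", 1:30))
  base_cn <- c(gypsy = 12L, copia = 6L, hat = 5L, mudr = 5L, harb = 5L)
  samples <- sprintf("s%d", 1:8)
  group <- rep(c("A", "B"), each = 4)
  libs <- list()
  for (i in 1:8) {
    cn <- base_cn
    if (group[i] == "B") cn[c("copia", "hat")] <- 2L * cn[c("copia", "hat")]
    specs <- lapply(names(shared), function(k)
      family_spec(shared[[k]]$id, shared[[k]]$cls, shared[[k]]$sf,
                  shared[[k]]$len, cn[[k]], 0.02,
                  consensus = shared[[k]]$seq))
    ref_i <- build_reference(specs, background_length = 2.5e5,
                             seed = derive_seed(seed, 100 + i), ucos = ucos)
    ## 80 bp libraries: after end-trimming, reads still reach the 60 bp
    ## clip target used by the equalized replicates
    prof <- library_profile(read_length = 80, mean_depth = 3,
                            base_error_rate = 0.01,
                            library_id = samples[i],
                            seed = derive_seed(seed, 200 + i))
    libs[[samples[i]]] <- trim_reads(simulate_reads(ref_i, prof))
  }
  contigs <- reference_contigs(
    c(setNames(vapply(shared, `[[`, "", "seq"),
               vapply(shared, `[[`, "", "id")), ucos),
    category = c(rep("TE", length(shared)), rep("UCOS", length(ucos))),
    te_class = c(vapply(shared, `[[`, "", "cls"), rep(NA, length(ucos))),
    superfamily = c(vapply(shared, `[[`, "", "sf"), rep(NA, length(ucos))))
  idx <- build_index(contigs)
  fingerprint_of <- function(lib_list, seed_offset) {
    tabs <- lapply(seq_along(lib_list), function(j) {
      set.seed(derive_seed(seed, seed_offset + j))
      aln <- map_reads(lib_list[[j]], idx)
      copy_number_table(pileup(aln, lib_list[[j]], contigs),
                        names(lib_list)[j])
    })
    names(tabs) <- names(lib_list)
    assemble_fingerprint(tabs)
  }
  full_matrix <- fingerprint_of(libs, 300)
  full_pca <- run_pca(full_matrix)
  separated <- function(p) {
    a <- p$scores[samples[group == "A"], 1]
    b <- p$scores[samples[group == "B"], 1]
    max(a) < min(b) || min(a) > max(b)
  }
  reps <- equalize_libraries(libs, target_length = 60,
                             n_replicates = n_replicates,
                             seed = derive_seed(seed, 13))
  rep_matrices <- lapply(seq_along(reps), function(r)
    fingerprint_of(reps[[r]], 400 + 10 * r))
  rep_pcas <- lapply(rep_matrices, run_pca)
  list(full_matrix = full_matrix, full_pca = full_pca,
       separated_full = separated(full_pca),
       pct_replicates_separated =
         100 * mean(vapply(rep_pcas, separated, logical(1))),
       stability = replicate_pca(rep_matrices, full_matrix)$stability)
}

## --- STAR phylogeny with discordant gene trees ----------------------------
## Six taxa (outgroup included), 100 gene trees of which 20% are random
## NNI perturbations of the species tree; multilocus bootstrap at B = 100.
experiment_phylogeny <- function(seed, n_trees = 100, discordant = 0.2,
                                 B = 100) {
  species <- ape::read.tree(
    text = "(((((A:1,B:1):1,C:2):1,D:3):1,E:4):1,O:5);")
  set.seed(derive_seed(seed, 14))
  n_disc <- round(discordant * n_trees)
  trees <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    trees[[i]] <- if (i <= n_trees - n_disc) species
    else phangorn::rNNI(species, moves = 2)
  }
  names(trees) <- sprintf("locus%03d", seq_len(n_trees))
  bs <- multilocus_bootstrap(trees, outgroup = "O", B = B,
                             seed = derive_seed(seed, 15))
  rf <- ape::dist.topo(ape::unroot(bs$tree), ape::unroot(species))
  list(bootstrap = bs, rf_to_truth = as.numeric(rf),
       support_AB = clade_support(bs, c("A", "B")))
}
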