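# UCOS phylogenetics: per-sample consensus calling on UCOS contigs, the
# gap-free concatenated matrix under the published filtering rules, NJ gene
# trees on JC69 distances, STAR species trees (average ranks of
# coalescences) and multilocus bootstrap support.

#' Call per-sample consensus sequences on reference contigs
#'
#' At each position, bases with quality at least the pileup's quality filter
#' are considered; positions with filtered depth below `min_depth` become N,
#' as do ambiguous positions whose top allele falls below
#' `majority_fraction` of the filtered depth (heterozygotes).
#'
#' @param pile A `pileup` for one sample.
#' @param min_depth Minimum filtered depth (default 6, i.e. 6 or more reads).
#' @param majority_fraction Minimum top-allele fraction to call a base.
#' @param contig_ids Contigs to call (default: all).
#' @return Named character vector of consensus sequences (A/C/G/T/N).
#' @export
consensus_sequences <- function(pile, min_depth = 6, majority_fraction = 0.8,
                                contig_ids = NULL) {
  if (is.null(contig_ids)) contig_ids <- names(pile$columns)
  out <- vapply(contig_ids, function(cid) {
    counts <- pile$columns[[cid]]$counts
    if (ncol(counts) == 0) return("")
    depth <- colSums(counts)
    top <- apply(counts, 2, max)
    base <- DNA_BASES[apply(counts, 2, which.max)]
    base[depth < min_depth | top < majority_fraction * depth] <- "N"
    paste(base, collapse = "")
  }, "")
  names(out) <- contig_ids
  out
}

#' Filter locus alignments to gap-free columns and usable loci
#'
#' Per locus, N's become gaps and every column containing at least one gap is
#' removed (nogap semantics); loci retaining fewer than `min_length` columns
#' are dropped. Survivors are concatenated into a single matrix with a
#' partition table recording each locus's coordinate range.
#'
#' @param loci Named list; each element is a named character vector of
#'   equal-length per-sample sequences for one locus.
#' @param min_length Minimum retained alignment length (default 50).
#' @return A `locus_matrix` list: `loci` (filtered per-locus alignments),
#'   `concatenated` (named character vector per sample), `partition` (data
#'   frame `locus`, `start`, `end`, 1-based inclusive), `dropped`.
#' @export
filter_columns_and_loci <- function(loci, min_length = 50) {
  samples <- Reduce(union, lapply(loci, names))
  kept <- list(); dropped <- character(0)
  for (nm in names(loci)) {
    seqs <- loci[[nm]]
    if (length(seqs) == 0 || all(!nzchar(seqs))) {
      dropped <- c(dropped, nm); next
    }
    chars <- do.call(rbind, strsplit(toupper(seqs), ""))
    good <- colSums(chars == "N" | chars == "-") == 0
    if (sum(good) < min_length) { dropped <- c(dropped, nm); next }
    m <- chars[, good, drop = FALSE]
    kept[[nm]] <- setNames(apply(m, 1, paste, collapse = ""), names(seqs))
  }
  if (length(kept) == 0)
    return(structure(list(loci = list(),
                          concatenated = setNames(rep("", length(samples)),
                                                  samples),
                          partition = data.frame(locus = character(0),
                                                 start = integer(0),
                                                 end = integer(0)),
                          dropped = dropped),
                     class = "locus_matrix"))
  lens <- vapply(kept, function(x) nchar(x[1]), 0L)
  ends <- cumsum(lens)
  starts <- c(1L, head(ends, -1) + 1L)
  partition <- data.frame(locus = names(kept), start = as.integer(starts),
                          end = as.integer(ends), stringsAsFactors = FALSE)
  concat <- vapply(samples, function(s)
    paste(vapply(kept, function(x) unname(x[s]), ""), collapse = ""), "")
  structure(list(loci = kept, concatenated = concat, partition = partition,
                 dropped = dropped),
            class = "locus_matrix")
}

#' Write a concatenated locus matrix as NEXUS with a partition block
#'
#' @param lm A `locus_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_nexus_matrix <- function(lm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  samples <- names(lm$concatenated)
  nchar_tot <- if (nrow(lm$partition) > 0) max(lm$partition$end) else 0
  writeLines("#NEXUS", con)
  writeLines("BEGIN DATA;", con)
  writeLines(sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(samples),
                     nchar_tot), con)
  writeLines("  FORMAT DATATYPE=DNA MISSING=? GAP=-;", con)
  writeLines("  MATRIX", con)
  for (s in samples)
    writeLines(sprintf("    %s %s", s, lm$concatenated[[s]]), con)
  writeLines("  ;", con)
  writeLines("END;", con)
  writeLines("BEGIN SETS;", con)
  for (i in seq_len(nrow(lm$partition)))
    writeLines(sprintf("  CHARSET %s = %d-%d;", lm$partition$locus[i],
                       lm$partition$start[i], lm$partition$end[i]), con)
  writeLines("END;", con)
  invisible(path)
}

## pairwise p-distance between equal-length gap-free sequences
p_distance_matrix <- function(seqs) {
  n <- length(seqs)
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- mean(chars[i, ] != chars[j, ])
    }
  }
  d
}

#' Neighbor-joining gene tree from a locus alignment
#'
#' Pairwise p-distances are Jukes-Cantor corrected
#' (`d = -3/4 log(1 - 4p/3)`) and passed to neighbor joining. Saturated
#' pairs (p >= 0.75) are an error.
#'
#' @param seqs Named character vector of equal-length aligned sequences
#'   (one per sample), at least 3.
#' @return An unrooted `phylo` tree.
#' @export
nj_gene_tree <- function(seqs) {
  if (length(seqs) < 3) stop_validation("gene tree needs at least 3 samples")
  if (length(unique(nchar(seqs))) != 1)
    stop_validation("aligned sequences must have equal length")
  p <- p_distance_matrix(seqs)
  if (any(p >= 0.75)) stop_validation("saturated p-distance (>= 0.75)")
  d <- -0.75 * log(1 - 4 * p / 3)
  ape::nj(as.dist(d))
}

## Assign STAR ranks: root rank = number of taxa in the tree; every internal
## child's rank is its parent's rank minus one (non-binary nodes give equal
## ranks to all children).
star_node_ranks <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  rank <- rep(NA_real_, n + tree$Nnode)
  rank[root] <- n
  ## process edges in preorder
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    if (child > n) rank[child] <- rank[parent] - 1
  }
  rank
}

## rank-distance matrix of one gene tree rooted on the outgroup:
## d(i, j) = 2 * rank(MRCA(i, j)); NULL if the outgroup is missing
star_rank_matrix <- function(tree, outgroup) {
  if (!(outgroup %in% tree$tip.label)) return(NULL)
  rtr <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  rank <- star_node_ranks(rtr)
  mr <- ape::mrca(rtr)
  d <- matrix(2 * rank[mr], nrow(mr), ncol(mr),
              dimnames = list(rtr$tip.label, rtr$tip.label))
  diag(d) <- 0
  d
}

## average per-pair rank distances over gene trees and neighbor-join
star_from_matrices <- function(mats, outgroup) {
  taxa <- sort(Reduce(union, lapply(mats, rownames)))
  nt <- length(taxa)
  dsum <- matrix(0, nt, nt, dimnames = list(taxa, taxa))
  dcount <- matrix(0, nt, nt, dimnames = list(taxa, taxa))
  for (m in mats) {
    labs <- rownames(m)
    dsum[labs, labs] <- dsum[labs, labs] + m
    dcount[labs, labs] <- dcount[labs, labs] + 1
  }
  if (any(dcount == 0 & upper.tri(dcount)))
    stop_validation("some taxon pairs never co-occur in a gene tree")
  dbar <- dsum / pmax(dcount, 1)
  diag(dbar) <- 0
  tree <- ape::nj(as.dist(dbar))
  tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  attr(tree, "rank_distance") <- dbar
  tree
}

#' STAR species tree from gene trees
#'
#' Each gene tree is rooted on the outgroup; internal nodes get coalescence
#' ranks (root = number of taxa, decreasing by one toward the tips); the
#' pairwise distance between two taxa in a gene tree is twice the rank of
#' their most recent common ancestor. Distances are averaged over the gene
#' trees containing both taxa and the species topology is estimated by
#' neighbor joining on the averaged matrix, rooted on the outgroup. Branch
#' lengths are in rank units, not substitutions.
#'
#' @param gene_trees List of `phylo` gene trees (or `multiPhylo`).
#' @param outgroup Outgroup tip label; trees lacking it are skipped with a
#'   warning.
#' @return A rooted `phylo` species tree with a `rank_distance` attribute.
#' @export
star_species_tree <- function(gene_trees, outgroup) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  mats <- lapply(gene_trees, star_rank_matrix, outgroup = outgroup)
  if (any(vapply(mats, is.null, logical(1))))
    warning("gene tree lacks the outgroup; skipped")
  mats <- Filter(Negate(is.null), mats)
  if (length(mats) == 0L)
    stop_validation("no usable gene trees (outgroup missing)")
  star_from_matrices(mats, outgroup)
}

#' Multilocus bootstrap support for a STAR species tree
#'
#' The point estimate is the STAR tree over all loci's gene trees. Each
#' bootstrap replicate resamples loci with replacement (sites within loci
#' are kept intact), reuses each locus's gene tree, and rebuilds the STAR
#' tree; internal edges of the point estimate are annotated with the
#' percentage of replicates containing the same bipartition, and a
#' majority-rule consensus of the replicate trees is returned as well.
#'
#' @param loci Named list of locus alignments (as in [filter_columns_and_loci()]
#'   output `loci`), or a list of precomputed `phylo` gene trees.
#' @param outgroup Outgroup tip label.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return A `star_bootstrap` list: `tree` (point estimate with `node.label`
#'   support percentages), `consensus`, `support`, `replicates`.
#' @export
multilocus_bootstrap <- function(loci, outgroup, B = 1000, seed = 1) {
  if (B < 1) stop_validation("B must be >= 1")
  if (length(loci) < 2) stop_validation("need at least 2 loci")
  gene_trees <- lapply(loci, function(l) {
    if (inherits(l, "phylo")) l else nj_gene_tree(l)
  })
  mats <- lapply(gene_trees, star_rank_matrix, outgroup = outgroup)
  if (any(vapply(mats, is.null, logical(1)))) {
    warning("dropping gene trees lacking the outgroup")
    mats <- Filter(Negate(is.null), mats)
  }
  if (length(mats) < 2) stop_validation("fewer than 2 usable loci")
  point <- star_from_matrices(mats, outgroup)
  set.seed(seed)
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- sample.int(length(mats), replace = TRUE)
    reps[[b]] <- star_from_matrices(mats[idx], outgroup)
  }
  class(reps) <- "multiPhylo"
  pc <- ape::prop.clades(point, reps, rooted = FALSE)
  pc[is.na(pc)] <- 0
  support <- 100 * pc / B
  point$node.label <- formatC(support, format = "f", digits = 0)
  cons <- ape::consensus(reps, p = 0.5)
  structure(list(tree = point, consensus = cons, support = support,
                 replicates = reps, B = B),
            class = "star_bootstrap")
}

#' Bootstrap support for one clade
#'
#' Percentage of bootstrap replicates containing the bipartition separating
#' `tips` from the rest.
#'
#' @param bs A `star_bootstrap`.
#' @param tips Tip labels of the clade of interest.
#' @return Support percentage.
#' @export
clade_support <- function(bs, tips) {
  hits <- vapply(bs$replicates, function(tr) {
    is_monophyletic_unrooted(tr, tips)
  }, logical(1))
  100 * mean(hits)
}

## bipartition check that ignores rooting
is_monophyletic_unrooted <- function(tree, tips) {
  labs <- tree$tip.label
  if (!all(tips %in% labs)) return(FALSE)
  other <- setdiff(labs, tips)
  ## splits isolating <= 1 tip on either side are present in every topology
  if (length(other) <= 1 || length(tips) <= 1) return(TRUE)
  ut <- ape::unroot(tree)
  bp <- ape::prop.part(ut)
  target <- sort(match(tips, ut$tip.label))
  comp <- sort(match(other, ut$tip.label))
  for (p in bp) {
    sp <- sort(p)
    if (identical(sp, target) || identical(sp, comp)) return(TRUE)
  }
  FALSE
}
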