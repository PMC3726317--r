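# De novo repeat detection: read-overlap graph (shared k-mer candidates,
# ungapped overlap scoring), Louvain communities, and cluster reports with
# genome percentages and repeat-library annotation.

#' Build a read-overlap graph
#'
#' Candidate read pairs share at least one exact k-mer (either orientation);
#' each candidate pair is scored by its best ungapped overlap and an edge is
#' added when identity is at least `min_identity` over an overlap of at
#' least `min_overlap_fraction` of the shorter read. Edge weight is
#' `identity * overlap_fraction`. If the read set exceeds `vertex_budget`,
#' reads are first subsampled to the budget (seeded), and downstream genome
#' percentages are ratios of the reads actually used.
#'
#' @param reads A `read_set` or character vector of read sequences.
#' @param k Candidate k-mer length (default 17).
#' @param min_identity Minimum overlap identity (default 0.90).
#' @param min_overlap_fraction Minimum overlap as a fraction of the shorter
#'   read (default 0.55).
#' @param max_candidates Candidate partner cap per read.
#' @param max_kmer_occ Occurrence cap per k-mer in the candidate table.
#' @param vertex_budget Maximum number of reads used in the graph.
#' @param seed Seed for the subsampling step.
#' @return A `read_graph` list: `edges` (data frame), `n_reads` (vertices),
#'   `used` (indices into the input read set), `params`.
#' @export
build_read_graph <- function(reads, k = 17, min_identity = 0.90,
                             min_overlap_fraction = 0.55,
                             max_candidates = 100, max_kmer_occ = 1000,
                             vertex_budget = 50000, seed = 1) {
  seqs <- if (is.character(reads)) reads else reads$sequence
  if (length(seqs) > 0 && min(nchar(seqs)) < k)
    stop_validation("k exceeds the shortest read length")
  used <- seq_along(seqs)
  if (length(seqs) > vertex_budget) {
    set.seed(seed)
    used <- sort(sample.int(length(seqs), vertex_budget))
    seqs <- seqs[used]
  }
  edges <- if (length(seqs) > 0)
    cpp_read_graph(toupper(seqs), as.integer(k), min_identity,
                   min_overlap_fraction, as.integer(max_candidates),
                   as.integer(max_kmer_occ))
  else data.frame(from = integer(0), to = integer(0), weight = numeric(0),
                  identity = numeric(0), overlap_fraction = numeric(0))
  structure(list(edges = edges, n_reads = length(seqs), used = used,
                 params = list(k = k, min_identity = min_identity,
                               min_overlap_fraction = min_overlap_fraction)),
            class = "read_graph")
}

#' Louvain repeat clusters of a read graph
#'
#' Modularity-maximizing Louvain partition of the overlap graph; isolated
#' reads form singleton communities. Because modularity optimization slices
#' the linear tiling graph of a long repeat into positional segments,
#' communities joined by substantial total edge weight (at least
#' `min_bridge_weight`) are then merged back, so each reported cluster spans
#' a whole repeat family while clusters connected only by an incidental weak
#' edge stay apart. Set `min_bridge_weight = Inf` for the raw Louvain
#' partition. Deterministic under the given seed.
#'
#' @param graph A `read_graph`.
#' @param resolution Louvain resolution parameter.
#' @param seed Integer seed.
#' @param min_bridge_weight Minimum summed inter-community edge weight that
#'   merges two communities (default 2, i.e. about two full-strength
#'   overlaps).
#' @return Integer vector of cluster labels, one per read used in the graph.
#' @export
louvain_clusters <- function(graph, resolution = 1.0, seed = 1,
                             min_bridge_weight = 2) {
  if (graph$n_reads == 0) return(integer(0))
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to", "weight")],
    directed = FALSE,
    vertices = data.frame(name = seq_len(graph$n_reads))
  )
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  mem <- igraph::membership(comm)
  part <- as.integer(mem[as.character(seq_len(graph$n_reads))])
  if (is.finite(min_bridge_weight) && nrow(graph$edges) > 0) {
    ca <- part[graph$edges$from]
    cb <- part[graph$edges$to]
    cross <- ca != cb
    if (any(cross)) {
      key <- paste(pmin(ca[cross], cb[cross]), pmax(ca[cross], cb[cross]))
      w <- tapply(graph$edges$weight[cross], key, sum)
      strong <- names(w)[w >= min_bridge_weight]
      if (length(strong) > 0) {
        ## union-find over communities to merge
        parent <- seq_len(max(part))
        find <- function(x) {
          while (parent[x] != x) {
            parent[x] <<- parent[parent[x]]
            x <- parent[x]
          }
          x
        }
        for (s in strong) {
          ab <- as.integer(strsplit(s, " ", fixed = TRUE)[[1]])
          ra <- find(ab[1]); rb <- find(ab[2])
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
        part <- vapply(part, find, 0L)
      }
    }
  }
  part
}

#' DUST-style low-complexity score
#'
#' Triplet-repetition score `sum(c_t * (c_t - 1) / 2) / (n_triplets - 1)`;
#' around 0.5 for random sequence, large for tandem or homopolymeric
#' sequence.
#'
#' @param seqs Character vector of sequences.
#' @return Numeric scores.
#' @export
dust_score <- function(seqs) {
  vapply(seqs, function(s) {
    L <- nchar(s)
    if (L < 4) return(0)
    tri <- substring(s, 1:(L - 2), 3:L)
    ct <- table(tri)
    sum(ct * (ct - 1) / 2) / (length(tri) - 1)
  }, 0, USE.NAMES = FALSE)
}

#' Report repeat clusters with genome percentages and annotation
#'
#' Clusters are sorted by size; each cluster's genome percentage is its read
#' count divided by the total reads used in the clustering, and clusters
#' below `cutoff` (default 0.01%, boundary inclusive) are omitted.
#' Annotation takes up to `n_representatives` member reads and computes
#' k-mer containment against each repeat-library sequence (both strands);
#' the best class above `min_containment` wins, otherwise clusters whose
#' representatives have a high mean DUST score are labelled
#' `"low complexity"` and the rest `"unknown"`.
#'
#' @param partition Community labels from [louvain_clusters()].
#' @param reads The reads used in the graph (character or `read_set`),
#'   aligned with `partition`.
#' @param repeat_library Named character vector of repeat reference
#'   sequences, or a named list mapping class labels to sequences; `NULL`
#'   disables sequence annotation.
#' @param cutoff Minimum genome percentage to report (percent; default 0.01).
#' @param annotation_k k-mer size for containment annotation.
#' @param min_containment Minimum mean containment to accept a library hit.
#' @param dust_threshold DUST score above which a cluster is low complexity.
#' @param n_representatives Reads sampled per cluster for annotation.
#' @return A `cluster_report` data frame: `cluster_id`, `n_reads`,
#'   `genome_percentage`, `annotation`; attribute `total_reads_used` and
#'   `members` (list of read indices per reported cluster).
#' @export
cluster_report <- function(partition, reads, repeat_library = NULL,
                           cutoff = 0.01, annotation_k = 17,
                           min_containment = 0.25, dust_threshold = 2,
                           n_representatives = 30) {
  total <- length(partition)
  if (total == 0) stop_validation("empty partition: no reads used")
  seqs <- if (is.character(reads)) reads else reads$sequence
  sizes <- sort(table(partition), decreasing = TRUE)
  pct <- 100 * as.numeric(sizes) / total
  keep <- pct >= cutoff
  ids <- names(sizes)[keep]
  members <- lapply(ids, function(cl) which(partition == as.integer(cl)))
  annotation <- vapply(members, function(m) {
    rep_idx <- if (length(m) > n_representatives)
      m[seq(1, length(m), length.out = n_representatives)] else m
    rep_seqs <- seqs[rep_idx]
    if (!is.null(repeat_library)) {
      cont <- library_containment(rep_seqs, repeat_library, annotation_k)
      if (max(cont) >= min_containment) return(names(cont)[which.max(cont)])
    }
    if (mean(dust_score(rep_seqs)) >= dust_threshold) return("low complexity")
    "unknown"
  }, "")
  out <- data.frame(
    cluster_id = sprintf("CL%d", seq_along(ids)),
    community = as.integer(ids),
    n_reads = as.integer(sizes[keep]),
    genome_percentage = pct[keep],
    annotation = annotation,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "total_reads_used") <- total
  attr(out, "members") <- setNames(members, out$cluster_id)
  class(out) <- c("cluster_report", "data.frame")
  out
}

## mean fraction of representative-read k-mers contained in each library
## class (both strands of the library sequence)
library_containment <- function(rep_seqs, repeat_library, k) {
  if (is.list(repeat_library))
    repeat_library <- unlist(repeat_library)
  kmers_of <- function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1), k:L))
  }
  read_kmers <- lapply(rep_seqs, kmers_of)
  per_seq <- vapply(seq_along(repeat_library), function(i) {
    lib <- repeat_library[[i]]
    lk <- unique(c(kmers_of(lib), kmers_of(revcomp(lib))))
    mean(vapply(read_kmers, function(ks) {
      if (length(ks) == 0) return(0)
      mean(ks %in% lk)
    }, 0))
  }, 0)
  ## multiple library sequences may share a class label; take the best
  agg <- tapply(per_seq, names(repeat_library), max)
  setNames(as.numeric(agg), names(agg))
}
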