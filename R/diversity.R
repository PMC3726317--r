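# Nucleotide variability of TE contigs: variable-site calling from pileup
# allele tallies, per-contig diversity (variable sites / contig length), and
# partitioning of LTR-element variability across element features.

#' Call variable sites on reference contigs
#'
#' A site is variable iff the quality-filtered depth is at least `min_depth`
#' ("read depth higher than 6" at the defaults), some non-reference base is
#' supported by at least `min_alt_support` reads of quality at least
#' `min_base_quality`, and that base's fraction of the filtered depth is at
#' least `min_alt_fraction`. Bases below `min_base_quality` are ignored
#' entirely (the pileup's allele tallies are already quality-filtered). A
#' variable site may reflect heterozygosity or divergence between element
#' copies; the two are deliberately not separated.
#'
#' @param pile A `pileup` built with `min_base_quality` matching the intended
#'   quality filter.
#' @param min_depth Minimum quality-filtered depth (default 7, i.e. strictly
#'   more than 6 reads).
#' @param min_alt_support Minimum reads supporting the alternative base.
#' @param min_alt_fraction Minimum alternative-allele fraction.
#' @param contig_ids Contigs to call on (default: all in the pileup).
#' @return Data frame of variant sites: `contig_id`, `pos` (0-based),
#'   `ref_base`, `alt_base`, `depth`, `alt_count`, `alt_fraction`.
#' @export
call_variant_sites <- function(pile, min_depth = 7, min_alt_support = 2,
                               min_alt_fraction = 0.2, contig_ids = NULL) {
  if (is.null(contig_ids)) contig_ids <- names(pile$columns)
  res <- lapply(contig_ids, function(cid) {
    counts <- pile$columns[[cid]]$counts
    refseq <- pile$contigs$sequence[match(cid, pile$contigs$contig_id)]
    L <- ncol(counts)
    if (L == 0) return(NULL)
    depth <- colSums(counts)
    ref <- match(strsplit(toupper(refseq), "")[[1]], DNA_BASES)
    alt_counts <- counts
    ok_ref <- !is.na(ref)
    ## zero out the reference row at each position
    idx <- cbind(ref[ok_ref], which(ok_ref))
    alt_counts[idx] <- 0L
    alt_best <- apply(alt_counts, 2, max)
    alt_base <- DNA_BASES[apply(alt_counts, 2, which.max)]
    callable <- depth >= min_depth & alt_best >= min_alt_support &
      alt_best / pmax(depth, 1) >= min_alt_fraction & ok_ref
    if (!any(callable)) return(NULL)
    p <- which(callable)
    data.frame(contig_id = cid, pos = p - 1L,
               ref_base = DNA_BASES[ref[p]], alt_base = alt_base[p],
               depth = depth[p], alt_count = alt_best[p],
               alt_fraction = alt_best[p] / depth[p],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(contig_id = character(0), pos = integer(0),
                      ref_base = character(0), alt_base = character(0),
                      depth = integer(0), alt_count = integer(0),
                      alt_fraction = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-contig nucleotide diversity
#'
#' Number of variable sites on a contig divided by the contig length.
#' Zero-variant contigs yield 0; for log10-scale plotting such zeros are
#' floored at `1 / (2 * contig_length)` in the `log10_diversity` column.
#'
#' @param variants Output of [call_variant_sites()].
#' @param contigs The `reference_contigs` the variants were called on.
#' @return Data frame: `contig_id`, `superfamily`, `te_class`, `n_variants`,
#'   `length`, `diversity`, `log10_diversity`.
#' @export
nucleotide_diversity <- function(variants, contigs) {
  n <- table(factor(variants$contig_id, levels = contigs$contig_id))
  len <- nchar(contigs$sequence)
  if (any(len == 0)) stop_validation("zero-length contig")
  div <- as.numeric(n) / len
  floor_val <- 1 / (2 * len)
  data.frame(contig_id = contigs$contig_id,
             superfamily = contigs$superfamily,
             te_class = contigs$te_class,
             n_variants = as.integer(n), length = len, diversity = div,
             log10_diversity = log10(pmax(div, floor_val)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize diversity per superfamily
#'
#' @param div Output of [nucleotide_diversity()].
#' @return Data frame of per-superfamily median and quartiles of diversity.
#' @export
diversity_summary <- function(div) {
  sf <- split(div$diversity, div$superfamily)
  data.frame(
    superfamily = names(sf),
    n_families = vapply(sf, length, 0L),
    median_diversity = vapply(sf, median, 0),
    q25 = vapply(sf, function(x) unname(quantile(x, 0.25)), 0),
    q75 = vapply(sf, function(x) unname(quantile(x, 0.75)), 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

GENE_FEATURES <- c("GAG", "AP", "RT", "RH", "IT", "other_gene")

#' Partition variant counts across LTR-element features
#'
#' Each variant is assigned to exactly one class by position, with precedence
#' internal genes (GAG/AP/RT/RH/IT/other_gene) > LTR > outside. The report
#' gives per-class counts, percentages of total variants, summed feature
#' lengths across contigs and per-bp rates (count / summed length).
#'
#' @param variants Output of [call_variant_sites()].
#' @param annotations Feature annotation data frame (`contig_id`, `feature`,
#'   `start`, `end`; 0-based half-open), e.g. from [read_feature_gff3()].
#' @param contigs The annotated `reference_contigs`; only annotated contigs
#'   are partitioned, and their unannotated span forms the `outside` class.
#' @param strict Error on variants falling on unannotated contigs.
#' @return A `partition_report` data frame with one row per feature class
#'   plus `outside`; attributes `total_variants` and `total_length`.
#' @export
partition_variants <- function(variants, annotations, contigs, strict = FALSE) {
  ann_contigs <- unique(annotations$contig_id)
  if (strict && length(setdiff(unique(variants$contig_id), ann_contigs)) > 0)
    stop_validation("variant on unannotated contig in strict mode")
  v <- variants[variants$contig_id %in% ann_contigs, , drop = FALSE]

  classify <- function(cid, pos) {
    a <- annotations[annotations$contig_id == cid, , drop = FALSE]
    hit <- a$feature[a$start <= pos & pos < a$end]
    genes <- intersect(hit, GENE_FEATURES)
    if (length(genes) > 0) return(genes[1])
    if ("LTR" %in% hit) return("LTR")
    if ("TIR" %in% hit) return("TIR")
    "outside"
  }
  cls <- if (nrow(v) > 0)
    mapply(classify, v$contig_id, v$pos, USE.NAMES = FALSE) else character(0)

  keep_contigs <- contigs[contigs$contig_id %in% ann_contigs, , drop = FALSE]
  total_len <- sum(nchar(keep_contigs$sequence))
  feat_levels <- c("LTR", GENE_FEATURES, "TIR")
  feat_len <- vapply(feat_levels, function(f) {
    a <- annotations[annotations$feature == f &
                       annotations$contig_id %in% keep_contigs$contig_id, ,
                     drop = FALSE]
    sum(a$end - a$start)
  }, 0)
  present <- feat_levels[feat_len > 0]
  lens <- c(feat_len[present], outside = total_len - sum(feat_len))
  counts <- vapply(names(lens), function(f) sum(cls == f), 0)
  total <- length(cls)
  out <- data.frame(
    feature = names(lens),
    variant_count = as.integer(counts),
    percent_of_total = if (total > 0) 100 * counts / total else rep(0, length(counts)),
    total_feature_length = as.numeric(lens),
    per_bp_rate = ifelse(lens > 0, counts / lens, NA_real_),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "total_variants") <- total
  attr(out, "total_length") <- total_len
  class(out) <- c("partition_report", "data.frame")
  out
}

## GFF3 type mapping used at the LTRharvest/LTRdigest-style boundary
GFF3_TYPE_TO_FEATURE <- c(
  long_terminal_repeat = "LTR",
  terminal_inverted_repeat = "TIR",
  RNase_H = "RH"
)

#' Write feature annotations as GFF3
#'
#' Internal 0-based half-open intervals become 1-based inclusive per the GFF3
#' standard. LTR and TIR intervals use Sequence Ontology types; internal ORFs
#' are written as `protein_match` records named by feature.
#'
#' @param annotations Data frame (`contig_id`, `feature`, `start`, `end`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_gff3 <- function(annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(annotations) > 0) {
    type <- ifelse(annotations$feature == "LTR", "long_terminal_repeat",
            ifelse(annotations$feature == "TIR", "terminal_inverted_repeat",
                   "protein_match"))
    attrs <- sprintf("ID=%s_%d;Name=%s", annotations$contig_id,
                     seq_len(nrow(annotations)), annotations$feature)
    writeLines(sprintf("%s\tteshot\t%s\t%d\t%d\t.\t+\t.\t%s",
                       annotations$contig_id, type,
                       annotations$start + 1L, annotations$end, attrs), con)
  }
  invisible(path)
}

#' Read LTR feature annotations from GFF3
#'
#' Accepts LTRharvest/LTRdigest-style output: `long_terminal_repeat` maps to
#' LTR, `protein_match` records map to GAG/AP/RT/RH/IT/other_gene by their
#' `Name` attribute, `terminal_inverted_repeat` maps to TIR; container
#' (`LTR_retrotransposon`, `repeat_region`) and `RR_tract` records are
#' ignored. GFF3 1-based inclusive coordinates become 0-based half-open.
#'
#' @param path GFF3 file.
#' @return Annotation data frame (`contig_id`, `feature`, `start`, `end`).
#' @export
read_feature_gff3 <- function(path) {
  g <- rtracklayer::readGFF(path)
  if (nrow(g) == 0)
    return(data.frame(contig_id = character(0), feature = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  type <- as.character(g$type)
  name <- if ("Name" %in% names(g)) as.character(g$Name) else
    rep(NA_character_, nrow(g))
  feature <- rep(NA_character_, length(type))
  feature[type == "long_terminal_repeat"] <- "LTR"
  feature[type == "terminal_inverted_repeat"] <- "TIR"
  is_pm <- type %in% c("protein_match", "nucleotide_to_protein_match")
  known <- c(GENE_FEATURES, "RH")
  feature[is_pm] <- ifelse(name[is_pm] %in% known, name[is_pm], "other_gene")
  keep <- !is.na(feature)
  data.frame(contig_id = as.character(g$seqid)[keep], feature = feature[keep],
             start = as.integer(g$start)[keep] - 1L,
             end = as.integer(g$end)[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}
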