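# UCOS-normalized abundance: per-contig mean coverage, the per-library UCOS
# baseline, relative copy numbers, superfamily totals/proportions and
# length-weighted genome fractions.

#' Mean coverage of a contig
#'
#' Arithmetic mean of per-position depth over the full contig length;
#' uncovered positions count as zero. Equals the summed aligned read length
#' divided by the contig length.
#'
#' @param coverage Integer vector of per-position depth.
#' @return Mean coverage.
#' @export
contig_mean_coverage <- function(coverage) {
  if (length(coverage) < 1) stop_validation("empty coverage array")
  mean(coverage)
}

#' UCOS baseline coverage of a library
#'
#' Unweighted mean over UCOS contigs of each contig's mean coverage; every
#' contig contributes equally regardless of length. This is the single-copy
#' sequencing-depth baseline that TE coverage is divided by.
#'
#' @param pile A `pileup` over (at least) the UCOS contigs.
#' @param ucos_ids Contig ids to use; defaults to contigs with category
#'   `"UCOS"`.
#' @param pooled If `TRUE`, use the base-weighted pooled mean instead
#'   (total aligned bases over total UCOS length).
#' @return Baseline coverage (fold).
#' @export
ucos_baseline <- function(pile, ucos_ids = NULL, pooled = FALSE) {
  if (is.null(ucos_ids))
    ucos_ids <- pile$contigs$contig_id[pile$contigs$category == "UCOS"]
  ucos_ids <- intersect(ucos_ids, names(pile$columns))
  if (length(ucos_ids) == 0) stop_validation("no UCOS contigs in pileup")
  covs <- lapply(pile$columns[ucos_ids], `[[`, "coverage")
  if (pooled) {
    sum(vapply(covs, sum, 0)) / sum(vapply(covs, length, 0L))
  } else {
    mean(vapply(covs, mean, 0))
  }
}

#' Relative copy number of a family
#'
#' Family mean coverage divided by the UCOS baseline; zero coverage maps to
#' zero copies.
#'
#' @param family_coverage Mean coverage of the family contig.
#' @param baseline UCOS baseline coverage (> 0).
#' @return Relative copy number.
#' @export
relative_copy_number <- function(family_coverage, baseline) {
  if (any(baseline <= 0)) stop_validation("UCOS baseline must be > 0")
  family_coverage / baseline
}

#' Build a copy-number table for one library
#'
#' Computes per-family mean coverage, the UCOS baseline and relative copy
#' numbers, plus superfamily totals and proportional abundances (each
#' superfamily total divided by the total over all TEs).
#'
#' @param pile A `pileup` covering TE and UCOS contigs.
#' @param sample_id Sample label.
#' @param ucos_ids Optional explicit UCOS contig ids.
#' @return A `copy_number_table` list: `sample_id`, `ucos_baseline`,
#'   `families` (per-family data frame) and `superfamilies`.
#' @export
copy_number_table <- function(pile, sample_id = "sample", ucos_ids = NULL) {
  contigs <- pile$contigs
  te <- contigs[contigs$category == "TE", , drop = FALSE]
  if (any(is.na(te$superfamily)))
    stop_validation("every TE family needs a superfamily label")
  baseline <- ucos_baseline(pile, ucos_ids)
  fam_cov <- vapply(pile$columns[te$contig_id],
                    function(x) mean(x$coverage), 0)
  fam <- data.frame(
    family_id = te$contig_id, superfamily = te$superfamily,
    te_class = te$te_class, contig_length = nchar(te$sequence),
    mean_coverage = unname(fam_cov),
    relative_copy_number = unname(relative_copy_number(fam_cov, baseline)),
    stringsAsFactors = FALSE
  )
  structure(list(sample_id = sample_id, ucos_baseline = baseline,
                 families = fam,
                 superfamilies = superfamily_abundance(fam)),
            class = "copy_number_table")
}

#' Aggregate family copy numbers to superfamilies
#'
#' Superfamily totals sum member families' relative copy numbers (a
#' count-like quantity, unweighted by length); proportional abundance
#' normalizes the totals to 1 across superfamilies. When all totals are zero
#' an empty data frame is returned rather than NaN proportions.
#'
#' @param families Per-family data frame with `superfamily` and
#'   `relative_copy_number` (as in a `copy_number_table`).
#' @return Data frame with `superfamily`, `total_copy_number`,
#'   `proportional_abundance`.
#' @export
superfamily_abundance <- function(families) {
  if (inherits(families, "copy_number_table")) families <- families$families
  if (any(is.na(families$superfamily)))
    stop_validation("unlabeled family in superfamily aggregation")
  tot <- tapply(families$relative_copy_number, families$superfamily, sum)
  out <- data.frame(superfamily = names(tot), total_copy_number = as.numeric(tot),
                    stringsAsFactors = FALSE)
  if (sum(out$total_copy_number) <= 0)
    return(data.frame(superfamily = character(0), total_copy_number = numeric(0),
                      proportional_abundance = numeric(0)))
  out$proportional_abundance <- out$total_copy_number / sum(out$total_copy_number)
  rownames(out) <- NULL
  out
}

#' Genome fraction occupied by each superfamily
#'
#' Length-weighted: for each family, relative copy number times consensus
#' length gives the base pairs attributed to the family; summed per
#' superfamily and divided by genome size.
#'
#' @param table A `copy_number_table`.
#' @param genome_size Haploid genome size in bp.
#' @return Data frame with `superfamily`, `bases`, `fraction`.
#' @export
genome_fraction <- function(table, genome_size) {
  if (genome_size <= 0) stop_validation("genome_size must be > 0")
  fam <- table$families
  if (any(is.na(fam$contig_length)))
    stop_validation("missing consensus length")
  bases <- fam$relative_copy_number * fam$contig_length
  tot <- tapply(bases, fam$superfamily, sum)
  data.frame(superfamily = names(tot), bases = as.numeric(tot),
             fraction = as.numeric(tot) / genome_size,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Genome fraction of each family
#'
#' Per-family variant of [genome_fraction()].
#'
#' @param table A `copy_number_table`.
#' @param genome_size Haploid genome size in bp.
#' @return Data frame with `family_id`, `superfamily`, `fraction`.
#' @export
family_genome_fraction <- function(table, genome_size) {
  if (genome_size <= 0) stop_validation("genome_size must be > 0")
  fam <- table$families
  data.frame(family_id = fam$family_id, superfamily = fam$superfamily,
             fraction = fam$relative_copy_number * fam$contig_length / genome_size,
             stringsAsFactors = FALSE)
}
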