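# Family specifications for the synthetic genome: TE class, superfamily,
# copy number, per-copy divergence and the internal feature layout used by
# the variability-partitioning stage.

TE_SUPERFAMILIES <- c("LTR/Gypsy", "LTR/Copia", "DNA/hAT", "DNA/Mutator",
                      "DNA/Harbinger", "Satellite")

LTR_GENE_FEATURES <- c("GAG", "AP", "RT", "RH", "IT")

#' Specify a TE family for the synthetic genome
#'
#' Describes one repeat family: a class I LTR retrotransposon (two long
#' terminal repeats flanking GAG/AP/RT/RH/IT open reading frames), a class II
#' cut-and-paste DNA transposon (transposase between terminal inverted
#' repeats), or a tandem satellite. Copies inserted into the genome diverge
#' from the family consensus by i.i.d. substitutions at rate
#' `per_copy_divergence`.
#'
#' @param family_id Unique family identifier.
#' @param te_class One of `"I"`, `"II"`, `"satellite"`.
#' @param superfamily Superfamily label (e.g. `"LTR/Gypsy"`, `"DNA/hAT"`).
#' @param consensus_length Consensus length in bp.
#' @param copy_number Number of copies inserted per haploid genome (>= 0).
#' @param per_copy_divergence Expected substitutions per site in [0, 0.5) by
#'   which each copy differs from the consensus.
#' @param feature_layout Optional data frame (`feature`, `start`, `end`;
#'   0-based half-open) overriding [default_feature_layout()].
#' @param consensus Optional explicit consensus sequence; drawn at random if
#'   `NULL`. Satellite consensus sequences are tandem tilings of a short
#'   monomer.
#' @param monomer_length Monomer length for satellite families.
#' @return A `family_spec` list.
#' @export
family_spec <- function(family_id, te_class = c("I", "II", "satellite"),
                        superfamily, consensus_length, copy_number,
                        per_copy_divergence = 0, feature_layout = NULL,
                        consensus = NULL, monomer_length = 12L) {
  te_class <- match.arg(te_class)
  if (copy_number < 0) stop_validation("copy_number must be >= 0")
  if (per_copy_divergence < 0 || per_copy_divergence >= 0.5)
    stop_validation("per_copy_divergence must lie in [0, 0.5)")
  if (consensus_length < 20) stop_validation("consensus_length too short")
  if (!is.null(consensus) && nchar(consensus) != consensus_length)
    stop_validation("explicit consensus length disagrees with consensus_length")
  if (is.null(feature_layout)) {
    feature_layout <- default_feature_layout(te_class, consensus_length)
  } else {
    validate_feature_layout(feature_layout, te_class, consensus_length)
  }
  structure(list(
    family_id = as.character(family_id), te_class = te_class,
    superfamily = as.character(superfamily),
    consensus_length = as.integer(consensus_length),
    copy_number = as.integer(copy_number),
    per_copy_divergence = per_copy_divergence,
    feature_layout = feature_layout, consensus = consensus,
    monomer_length = as.integer(monomer_length)
  ), class = "family_spec")
}

#' Default feature layout of a TE consensus
#'
#' Class I elements carry a 5' and 3' long terminal repeat (LTR) of equal
#' length plus internal GAG, AP, RT, RH and IT open reading frames, with
#' unannotated spacer in between; class II elements carry two terminal
#' inverted repeats (TIR) around a transposase. Satellites have no features.
#' Intervals are 0-based half-open on the consensus.
#'
#' @param te_class `"I"`, `"II"` or `"satellite"`.
#' @param consensus_length Consensus length in bp.
#' @return Data frame with columns `feature`, `start`, `end`.
#' @export
default_feature_layout <- function(te_class, consensus_length) {
  L <- consensus_length
  at <- function(a, b) c(floor(a * L), floor(b * L))
  if (te_class == "I") {
    segs <- rbind(
      data.frame(feature = "LTR", start = 0, end = floor(0.12 * L)),
      data.frame(feature = "GAG", start = at(0.18, 0.28)[1], end = at(0.18, 0.28)[2]),
      data.frame(feature = "AP",  start = at(0.30, 0.36)[1], end = at(0.30, 0.36)[2]),
      data.frame(feature = "RT",  start = at(0.40, 0.52)[1], end = at(0.40, 0.52)[2]),
      data.frame(feature = "RH",  start = at(0.54, 0.60)[1], end = at(0.54, 0.60)[2]),
      data.frame(feature = "IT",  start = at(0.62, 0.72)[1], end = at(0.62, 0.72)[2]),
      data.frame(feature = "LTR", start = L - floor(0.12 * L), end = L)
    )
  } else if (te_class == "II") {
    tir <- max(10L, floor(0.05 * L))
    segs <- rbind(
      data.frame(feature = "TIR", start = 0, end = tir),
      data.frame(feature = "other_gene", start = at(0.2, 0.8)[1], end = at(0.2, 0.8)[2]),
      data.frame(feature = "TIR", start = L - tir, end = L)
    )
  } else {
    segs <- data.frame(feature = character(), start = integer(), end = integer())
  }
  segs$start <- as.integer(segs$start)
  segs$end <- as.integer(segs$end)
  segs
}

validate_feature_layout <- function(layout, te_class, consensus_length) {
  if (!all(c("feature", "start", "end") %in% names(layout)))
    stop_validation("feature_layout needs feature/start/end columns")
  if (any(layout$start < 0) || any(layout$end > consensus_length) ||
      any(layout$end <= layout$start))
    stop_validation("feature intervals must be non-empty and within [0, consensus_length)")
  o <- order(layout$start)
  s <- layout$start[o]; e <- layout$end[o]
  if (any(s[-1] < e[-length(e)]))
    stop_validation("feature intervals must be disjoint")
  if (te_class == "I") {
    ltr <- layout[layout$feature == "LTR", , drop = FALSE]
    if (nrow(ltr) == 2 && diff(ltr$end - ltr$start) != 0)
      stop_validation("the two LTR intervals must have equal length")
  }
  invisible(layout)
}
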