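# TE-composition fingerprinting: sample x superfamily abundance matrices,
# PCA on natural-log-transformed unit-variance-scaled columns, and stability
# assessment across equalized subsample replicates.

#' Assemble a fingerprint matrix across samples
#'
#' Rows are samples, columns TE superfamilies, values relative copy numbers.
#' All samples must share the same superfamily set. Zero cells are floored at
#' half the smallest positive value in their column so the downstream log
#' transform is defined; the floor per column is recorded in the
#' `zero_floor` attribute.
#'
#' @param tables Named list of `copy_number_table` objects (or of named
#'   numeric vectors of superfamily abundances).
#' @return A numeric matrix of class `fingerprint_matrix`.
#' @export
assemble_fingerprint <- function(tables) {
  vecs <- lapply(tables, function(t) {
    if (inherits(t, "copy_number_table"))
      setNames(t$superfamilies$total_copy_number, t$superfamilies$superfamily)
    else unlist(t)
  })
  cols <- sort(unique(unlist(lapply(vecs, names))))
  for (i in seq_along(vecs)) {
    missing <- setdiff(cols, names(vecs[[i]]))
    if (length(missing) > 0)
      stop_validation("sample ", names(vecs)[i] %||% i,
                      " is missing superfamily: ", missing[1])
  }
  m <- do.call(rbind, lapply(vecs, `[`, cols))
  rownames(m) <- names(tables) %||% sprintf("sample%d", seq_along(tables))
  colnames(m) <- cols
  floors <- apply(m, 2, function(x) {
    pos <- x[x > 0]
    if (length(pos) == 0) 0 else min(pos) / 2
  })
  for (j in seq_len(ncol(m))) m[m[, j] == 0, j] <- floors[j]
  attr(m, "zero_floor") <- floors
  class(m) <- c("fingerprint_matrix", class(m))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' PCA of a fingerprint matrix
#'
#' Columns are natural-log transformed, centered and scaled to unit variance
#' (`prcomp(..., scale. = TRUE)` semantics); zero-variance columns are
#' dropped with a warning. The sign of each component is fixed so its
#' largest-magnitude loading is positive, making replicate runs comparable
#' without Procrustes rotation.
#'
#' @param m A `fingerprint_matrix` (samples x superfamilies, positive).
#' @param log_transform Apply the natural log first (default `TRUE`).
#' @return A `te_pca` list: `scores` (samples x PCs), `loadings`
#'   (superfamilies x PCs), `explained` (variance proportions), `sdev`.
#' @export
run_pca <- function(m, log_transform = TRUE) {
  if (nrow(m) < 2) stop_validation("PCA needs at least 2 samples")
  x <- unclass(m)
  if (log_transform) {
    if (any(x <= 0)) stop_validation("log transform needs positive values")
    x <- log(x)
  }
  v <- apply(x, 2, var)
  if (all(v == 0)) stop_validation("all columns have zero variance")
  if (any(v == 0)) {
    warning("dropping zero-variance columns: ",
            paste(colnames(x)[v == 0], collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
  }
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(p$rotation, 2, function(l) {
    if (l[which.max(abs(l))] < 0) -1 else 1
  })
  scores <- sweep(p$x, 2, flip, `*`)
  loadings <- sweep(p$rotation, 2, flip, `*`)
  explained <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 explained = explained, sdev = p$sdev),
            class = "te_pca")
}

#' @export
print.te_pca <- function(x, ...) {
  cat("PCA of TE superfamily fingerprint\n")
  cat(sprintf("  %d samples, %d superfamilies\n",
              nrow(x$scores), nrow(x$loadings)))
  pct <- round(100 * x$explained[seq_len(min(3, length(x$explained)))], 1)
  cat("  explained variance (%):", paste(pct, collapse = ", "), "...\n")
  invisible(x)
}

#' PCA across subsample replicates with a stability summary
#'
#' Runs the fingerprint PCA on each replicate matrix and compares sample
#' scores on PC1/PC2 against the full-data PCA by sign-aligned Pearson
#' correlation (absolute value of the correlation, since component signs are
#' arbitrary up to the fixed convention).
#'
#' @param replicate_matrices List of `fingerprint_matrix` objects (same
#'   samples as `full`).
#' @param full The full-data `fingerprint_matrix`.
#' @return A `replicate_pca` list: `full_pca`, `replicates` (list of
#'   `te_pca`), `stability` (per-replicate PC1/PC2 score correlations).
#' @export
replicate_pca <- function(replicate_matrices, full) {
  full_pca <- run_pca(full)
  reps <- lapply(replicate_matrices, run_pca)
  stability <- if (length(reps) >= 1) {
    do.call(rbind, lapply(seq_along(reps), function(i) {
      r <- reps[[i]]
      samples <- rownames(full_pca$scores)
      data.frame(
        replicate = i,
        cor_pc1 = abs(cor(full_pca$scores[samples, 1],
                          r$scores[samples, 1])),
        cor_pc2 = if (ncol(r$scores) >= 2 && ncol(full_pca$scores) >= 2)
          abs(cor(full_pca$scores[samples, 2], r$scores[samples, 2]))
        else NA_real_
      )
    }))
  } else data.frame(replicate = integer(0), cor_pc1 = numeric(0),
                    cor_pc2 = numeric(0))
  structure(list(full_pca = full_pca, replicates = reps,
                 stability = stability),
            class = "replicate_pca")
}
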