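#' Full-quantile normalization across cells
#'
#' Forces every cell (column) to share one common empirical distribution:
#' within each cell, the value of rank r is replaced by the mean across
#' cells of the r-th order statistic. Ties within a cell receive the mean of
#' the reference quantiles their rank block spans, so equal input values map
#' to equal output values and the zero block of a cell maps to the average
#' of the lowest reference quantiles.
#'
#' @param x genes-by-cells numeric matrix (or SingleCellExperiment, in
#'   which case `layer` selects the assay).
#' @param layer assay name when `x` is an experiment object.
#' @return Matrix of the same shape and dimnames; each column's sorted
#'   values equal the common reference distribution.
#' @examples
#' m <- cbind(A = c(1, 2, 3), B = c(30, 10, 20))
#' quantileNormalize(m)  # A -> 5.5, 11, 16.5; B -> 16.5, 5.5, 11
#' @export
quantileNormalize <- function(x, layer = "counts") {
  m <- get_layer(x, layer)
  if (ncol(m) < 2L)
    stopf("quantile normalization needs at least 2 cells (got %d)", ncol(m))
  sorted <- apply(m, 2L, sort)
  ref <- rowMeans(sorted)
  cref <- cumsum(ref)
  out <- m
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    rmin <- rank(v, ties.method = "min")
    rmax <- rank(v, ties.method = "max")
    # mean of ref[rmin:rmax] for each tie block, via cumulative sums
    out[, j] <- (cref[rmax] - c(0, cref)[rmin]) / (rmax - rmin + 1)
  }
  out
}

#' Log transform with pseudocount
#'
#' Natural log of (value + pseudocount); with the default pseudocount of 1,
#' zeros map to zero and the transform is strictly monotone.
#'
#' @param x non-negative matrix or SingleCellExperiment.
#' @param pseudocount added before taking the log (default 1).
#' @param layer assay to transform when `x` is an experiment object.
#' @return Transformed matrix.
#' @export
logTransform <- function(x, pseudocount = 1, layer = "quantile_norm") {
  m <- get_layer(x, layer)
  if (any(m < 0)) stopf("log transform requires non-negative values")
  log(m + pseudocount)
}

#' Per-gene scaling to zero mean and unit standard deviation
#'
#' Subtracts each gene's mean across cells and divides by its standard
#' deviation (n - 1 divisor). Genes with zero variance are mapped to
#' all-zeros with a warning rather than producing NaN.
#'
#' @param x matrix or SingleCellExperiment.
#' @param layer assay to scale when `x` is an experiment object.
#' @return Scaled matrix; every non-constant gene has mean 0 and sd 1.
#' @export
scaleGenes <- function(x, layer = "lognorm") {
  m <- get_layer(x, layer)
  if (ncol(m) < 2L) stopf("scaling needs at least 2 cells")
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
  zero <- sdv == 0
  if (any(zero)) {
    warnf("%d zero-variance gene(s) scaled to all-zeros", sum(zero))
    sdv[zero] <- 1
  }
  out <- (m - mu) / sdv
  out[zero, ] <- 0
  out
}

#' Full normalization stack
#'
#' Adds the three derived layers to the experiment: `quantile_norm`
#' (full-quantile normalization of counts across cells), `lognorm`
#' (natural log with pseudocount) and `scaled` (per-gene standardization
#' of lognorm).
#'
#' @param sce SingleCellExperiment with a `counts` assay, already QC
#'   filtered.
#' @param pseudocount for the log transform (default 1).
#' @return The experiment with assays counts, quantile_norm, lognorm,
#'   scaled.
#' @export
normalizeExpression <- function(sce, pseudocount = 1) {
  qn <- quantileNormalize(sce, layer = "counts")
  SummarizedExperiment::assay(sce, "quantile_norm") <- qn
  ln <- log(qn + pseudocount)
  SummarizedExperiment::assay(sce, "lognorm") <- ln
  SummarizedExperiment::assay(sce, "scaled") <-
    suppressWarnings(scaleGenes(ln))
  sce
}
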