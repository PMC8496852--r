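#' Per-cell quality-control thresholds
#'
#' The default profile encodes the four criteria used to select cells from
#' the patient plates: mapping rate strictly above 30%, more than 100,000
#' reads, between 1,800 and 15,000 detected genes (inclusive), and a
#' mitochondrial read fraction strictly below 12.5%; plus the per-gene
#' prevalence rule that a gene must be detected in at least 10 passing cells.
#' The "healthy_donor" profile is the looser preselection used for the
#' public 10x effector-memory reference cells (reads > 2,400, detected genes
#' 850-2,000).
#'
#' @param min_mapping_rate,min_reads,min_genes,max_genes,max_mito_fraction,min_cells_per_gene
#'   threshold overrides; see Details for boundary semantics.
#' @param profile "patient" (default) or "healthy_donor".
#' @details Boundary semantics follow the stated criteria literally:
#'   mapping rate, read count and mitochondrial fraction are strict
#'   inequalities; the detected-gene range is inclusive on both ends; genes
#'   are retained when detected in `min_cells_per_gene` or more cells.
#' @return A named list of thresholds with class "QcThresholds".
#' @examples
#' qcThresholds()
#' qcThresholds(profile = "healthy_donor")
#' @export
qcThresholds <- function(min_mapping_rate = NULL, min_reads = NULL,
                         min_genes = NULL, max_genes = NULL,
                         max_mito_fraction = NULL, min_cells_per_gene = NULL,
                         profile = c("patient", "healthy_donor")) {
  profile <- match.arg(profile)
  th <- if (profile == "patient") {
    list(min_mapping_rate = 0.30, min_reads = 100000L,
         min_genes = 1800L, max_genes = 15000L,
         max_mito_fraction = 0.125, min_cells_per_gene = 10L)
  } else {
    list(min_mapping_rate = 0, min_reads = 2400L,
         min_genes = 850L, max_genes = 2000L,
         max_mito_fraction = 1, min_cells_per_gene = 10L)
  }
  ovr <- list(min_mapping_rate = min_mapping_rate, min_reads = min_reads,
              min_genes = min_genes, max_genes = max_genes,
              max_mito_fraction = max_mito_fraction,
              min_cells_per_gene = min_cells_per_gene)
  for (nm in names(ovr)) if (!is.null(ovr[[nm]])) th[[nm]] <- ovr[[nm]]
  if (!is_fraction(th$min_mapping_rate) || !is_fraction(th$max_mito_fraction))
    stopf("mapping-rate and mitochondrial-fraction thresholds must be fractions in [0, 1]")
  if (!th$min_genes < th$max_genes)
    stopf("min_genes (%s) must be below max_genes (%s)",
          th$min_genes, th$max_genes)
  structure(th, class = "QcThresholds")
}

qc_covariates <- c("mapping_rate", "total_reads", "n_genes_detected",
                   "mito_fraction")

qc_criteria <- c("mapping_rate", "total_reads", "n_genes_detected",
                 "mito_fraction")

#' Apply the four per-cell quality-control criteria
#'
#' A cell passes iff mapping_rate > min_mapping_rate AND total_reads >
#' min_reads AND min_genes <= n_genes_detected <= max_genes AND
#' mito_fraction < max_mito_fraction. The failure report counts cells
#' failing each criterion; the counts are non-exclusive (a cell failing
#' two criteria appears under both).
#'
#' @param cells a data.frame of per-cell metadata (or a
#'   SingleCellExperiment, in which case colData is used) with the columns
#'   mapping_rate, total_reads, n_genes_detected, mito_fraction and cell_id.
#' @param thresholds a [qcThresholds()] object.
#' @return A list with elements `pass` (character vector of passing cell
#'   ids), `fail` (failing ids), `report` (named integer vector of failure
#'   counts per criterion) and `flags` (logical matrix, cells x criteria,
#'   TRUE where the criterion failed).
#' @export
filterCells <- function(cells, thresholds = qcThresholds()) {
  df <- get_cell_table(cells)
  if (!"cell_id" %in% names(df)) stopf("cell table must have a cell_id column")
  for (col in qc_covariates) {
    if (!col %in% names(df))
      stopf("missing QC covariate column '%s'", col)
    bad <- which(is.na(df[[col]]))
    if (length(bad))
      stopf("missing QC covariate '%s' for cell '%s'", col,
            df$cell_id[bad[1]])
  }
  th <- thresholds
  fail <- cbind(
    mapping_rate = !(df$mapping_rate > th$min_mapping_rate),
    total_reads = !(df$total_reads > th$min_reads),
    n_genes_detected = !(df$n_genes_detected >= th$min_genes &
                           df$n_genes_detected <= th$max_genes),
    mito_fraction = !(df$mito_fraction < th$max_mito_fraction)
  )
  rownames(fail) <- df$cell_id
  ok <- rowSums(fail) == 0L
  list(pass = df$cell_id[ok],
       fail = df$cell_id[!ok],
       report = colSums(fail),
       flags = fail)
}

#' Per-gene prevalence filter
#'
#' Applied after cell filtering: a gene is retained iff it has a non-zero
#' count in at least `min_cells_per_gene` of the passing cells. The order
#' (cells first, then genes) is part of the contract.
#'
#' @param x SingleCellExperiment or counts matrix already restricted to
#'   QC-passing cells.
#' @param thresholds a [qcThresholds()] object (uses `min_cells_per_gene`).
#' @return Character vector of retained gene ids, in matrix order.
#' @export
filterGenes <- function(x, thresholds = qcThresholds()) {
  m <- if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts") else x
  ncells <- if (is(m, "sparseMatrix")) {
    Matrix::rowSums(m > 0)
  } else {
    rowSums(m > 0)
  }
  rownames(m)[ncells >= thresholds$min_cells_per_gene]
}

#' Run both QC stages and subset the experiment
#'
#' Convenience wrapper: [filterCells()] then [filterGenes()] on the
#' cell-restricted matrix, returning the subsetted experiment with the QC
#' report in its metadata.
#'
#' @inheritParams filterCells
#' @param sce SingleCellExperiment whose colData carries the QC covariates.
#' @return The subsetted SingleCellExperiment; `metadata(sce)$qc` holds the
#'   cell-level report.
#' @export
applyQc <- function(sce, thresholds = qcThresholds()) {
  res <- filterCells(sce, thresholds)
  out <- sce[, res$pass]
  keep <- filterGenes(out, thresholds)
  out <- out[keep, ]
  S4Vectors::metadata(out)$qc <- res[c("pass", "fail", "report")]
  out
}

#' Number of genes detected per cell
#'
#' Computes the detected-gene QC covariate (count > 0) from the counts
#' assay; upstream covariates (mapping rate, total reads) come from the
#' sequencing pipeline and cannot be derived from the matrix.
#'
#' @param x SingleCellExperiment or counts matrix.
#' @return Named integer vector, one entry per cell.
#' @export
detectedGenes <- function(x) {
  m <- if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts") else x
  n <- if (is(m, "sparseMatrix")) Matrix::colSums(m > 0) else colSums(m > 0)
  setNames(as.integer(n), colnames(m))
}
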