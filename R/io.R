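#' Read a gene-by-cell count matrix
#'
#' Reads either a Matrix Market triplet (`.mtx` plus one gene-label and one
#' cell-label text file, one identifier per line) or a dense tab-separated
#' matrix (header row of cell ids, first column of gene ids). Genes are rows,
#' cells are columns. The result is validated: identifiers must be unique and
#' counts non-negative integers.
#'
#' @param path path to the `.mtx` file (format "mtx") or the TSV (format
#'   "dense_tsv").
#' @param genes,cells label file paths, required for format "mtx".
#' @param format "mtx" or "dense_tsv".
#' @return A [SingleCellExperiment::SingleCellExperiment] with a single
#'   `counts` assay (sparse), gene ids as rownames and cell ids as colnames.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2), x = c(5, 3),
#'                           dims = c(3, 2))
#' rownames(m) <- paste0("G", 1:3); colnames(m) <- paste0("C", 1:2)
#' sce <- SingleCellExperiment::SingleCellExperiment(list(counts = m))
#' writeExpressionMatrix(sce, file.path(dir, "counts"), format = "mtx")
#' back <- readExpressionMatrix(file.path(dir, "counts.mtx"),
#'                              genes = file.path(dir, "counts.genes.txt"),
#'                              cells = file.path(dir, "counts.cells.txt"))
#' @export
readExpressionMatrix <- function(path, genes = NULL, cells = NULL,
                                 format = c("mtx", "dense_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "mtx") {
    if (is.null(genes) || is.null(cells))
      stopf("format 'mtx' requires 'genes' and 'cells' label files")
    for (f in c(genes, cells))
      if (!file.exists(f)) stopf("file not found: %s", f)
    # force a general storage class: symmetric/triangular Matrix Market
    # variants couple the two dimnames and would mislabel the axes
    m <- as(as(Matrix::readMM(path), "CsparseMatrix"), "generalMatrix")
    gid <- readLines(genes)
    cid <- readLines(cells)
    if (length(gid) != nrow(m))
      stopf("dimension mismatch: %s has %d labels but matrix has %d rows",
            genes, length(gid), nrow(m))
    if (length(cid) != ncol(m))
      stopf("dimension mismatch: %s has %d labels but matrix has %d columns",
            cells, length(cid), ncol(m))
    rownames(m) <- gid
    colnames(m) <- cid
  } else {
    tab <- read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                      check.names = FALSE, stringsAsFactors = FALSE)
    m <- as(as.matrix(tab), "CsparseMatrix")
  }
  validate_counts(m)
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

validate_counts <- function(m) {
  if (anyDuplicated(rownames(m)))
    stopf("duplicate gene identifiers: %s",
          paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stopf("duplicate cell identifiers: %s",
          paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  x <- if (is(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(x)) {
    if (any(x < 0)) stopf("counts must be non-negative")
    if (any(x != floor(x))) stopf("counts must be integral")
  }
  invisible(TRUE)
}

#' Write a count matrix (or any assay layer)
#'
#' For `format = "mtx"` writes `<prefix>.mtx`, `<prefix>.genes.txt` and
#' `<prefix>.cells.txt` (1-based Matrix Market, genes as rows). For
#' `format = "dense_tsv"` writes a single `<prefix>.tsv` with a header of
#' cell ids and a first column of gene ids. Writers are deterministic and
#' emit "\n" line endings.
#'
#' @param x SingleCellExperiment or matrix.
#' @param prefix output path prefix (no extension).
#' @param format "mtx" or "dense_tsv".
#' @param layer assay to write when `x` is a SingleCellExperiment.
#' @return Invisibly, the character vector of files written.
#' @export
writeExpressionMatrix <- function(x, prefix, format = c("mtx", "dense_tsv"),
                                  layer = "counts") {
  format <- match.arg(format)
  m <- if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, layer) else x
  if (format == "mtx") {
    files <- paste0(prefix, c(".mtx", ".genes.txt", ".cells.txt"))
    Matrix::writeMM(as(as(m, "CsparseMatrix"), "generalMatrix"), files[1])
    writeLines(rownames(m), files[2])
    writeLines(colnames(m), files[3])
  } else {
    files <- paste0(prefix, ".tsv")
    df <- data.frame(gene_id = rownames(m), as.matrix(m),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df, files)
  }
  invisible(files)
}

# Deterministic TSV writer used for all tabular outputs.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read a Broad-dialect GMT gene-set file
#'
#' Each line: set name, description, then one or more gene symbols, all
#' tab-separated. Genes duplicated within a line are dropped (first
#' occurrence kept); file order of sets and genes is preserved.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (the gene sets), with a
#'   `description` attribute carrying the per-set description strings.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warnf("GMT file '%s' contains no gene sets", path)
    return(structure(list(), description = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stopf("GMT parse error at line %d: expected >= 3 tab-separated fields, got %d",
          which(nf < 3)[1], nf[which(nf < 3)[1]])
  nm <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(nm))
    stopf("duplicate gene-set names: %s",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(parts, `[`, character(1), 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  names(desc) <- nm
  structure(sets, description = desc)
}

#' Write gene sets as GMT
#'
#' @param sets named list of character vectors; an optional `description`
#'   attribute (named as `sets`) supplies the second column.
#' @param path output path.
#' @export
writeGmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

tcr_required_cols <- c("cell_id", "locus", "v_gene", "j_gene",
                       "cdr3_nt", "cdr3_aa", "productive")

#' Read a TCR chain table
#'
#' Tab-separated table of reconstructed TCR chains, one row per chain, in the
#' shape TraCeR-style assemblers emit: cell_id, locus (TRA/TRB), v_gene,
#' j_gene, cdr3_nt, cdr3_aa, productive. Non-productive chains are retained
#' (flagged by the `productive` column); gamma/delta loci are rejected.
#'
#' @param path TSV path.
#' @return A validated data.frame of chains.
#' @export
readTcrTable <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  validateTcrTable(tab)
}

#' Validate a TCR chain table
#'
#' @param tab data.frame with the columns listed in [readTcrTable()].
#' @return The table, with `productive` coerced to logical.
#' @export
validateTcrTable <- function(tab) {
  missing <- setdiff(tcr_required_cols, names(tab))
  if (length(missing))
    stopf("TCR table missing required columns: %s",
          paste(missing, collapse = ", "))
  bad <- setdiff(unique(tab$locus), c("TRA", "TRB"))
  if (length(bad))
    stopf("unknown locus value(s): %s (only TRA and TRB chains are supported)",
          paste(bad, collapse = ", "))
  if (is.character(tab$productive))
    tab$productive <- toupper(tab$productive) %in% c("TRUE", "T", "1", "YES")
  tab$productive <- as.logical(tab$productive)
  key <- do.call(paste, c(tab[c("cell_id", "locus", "cdr3_nt",
                                "v_gene", "j_gene")], sep = "\r"))
  if (anyDuplicated(key))
    stopf("duplicate chain rows (cell_id, locus, cdr3_nt, v_gene, j_gene): %d",
          sum(duplicated(key)))
  tab
}

#' Read a per-cell metadata table
#'
#' @param path TSV with columns cell_id, patient, plate, tetramer_label,
#'   mapping_rate, total_reads, n_genes_detected, mito_fraction.
#' @return Validated data.frame.
#' @export
readCellTable <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!"cell_id" %in% names(tab)) stopf("cell table must have a cell_id column")
  if (anyDuplicated(tab$cell_id))
    stopf("duplicate cell ids: %s",
          paste(unique(tab$cell_id[duplicated(tab$cell_id)]), collapse = ", "))
  for (col in c("mapping_rate", "mito_fraction")) {
    if (col %in% names(tab) &&
        any(tab[[col]] < 0 | tab[[col]] > 1, na.rm = TRUE))
      stopf("column '%s' must lie in [0, 1]", col)
  }
  tab
}

#' Read a signed signature from a two-column TSV
#'
#' Column 1 is the gene symbol, column 2 the sign (+1/-1, or "up"/"down").
#'
#' @param path TSV path (header optional; detected from the first line).
#' @param name signature name; default the file base name.
#' @return A [SignedSignature-class].
#' @export
readSignature <- function(path, name = NULL) {
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  header <- suppressWarnings(is.na(as.numeric(first[2]))) &&
    !tolower(first[2]) %in% c("up", "down")
  tab <- read.delim(path, header = header, sep = "\t",
                    stringsAsFactors = FALSE,
                    col.names = c("gene", "sign"))
  s <- tolower(as.character(tab$sign))
  sign <- ifelse(s %in% c("1", "+1", "up"), 1,
                 ifelse(s %in% c("-1", "down"), -1, NA))
  if (anyNA(sign))
    stopf("unrecognized sign value(s): %s",
          paste(unique(tab$sign[is.na(sign)]), collapse = ", "))
  SignedSignature(name, up = tab$gene[sign > 0], down = tab$gene[sign < 0])
}

#' Write a signed signature as a two-column TSV
#' @param sig a [SignedSignature-class].
#' @param path output path.
#' @export
writeSignature <- function(sig, path) {
  w <- signatureWeights(sig)
  write_tsv(data.frame(gene = names(w), sign = as.integer(w)), path)
}
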