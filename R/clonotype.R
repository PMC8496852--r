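#' Assign cells to clonotypes from reconstructed TCR chains
#'
#' Within each patient, cells carrying at least one usable chain form the
#' nodes of a graph; two cells are connected when they share at least one
#' identical chain, where chain identity is the exact (locus, V gene,
#' J gene, CDR3) tuple — nucleotide CDR3 by default, amino-acid by option.
#' Clonotypes are the connected components (so chain sharing is closed
#' transitively: if A shares a beta chain with B and B an alpha chain with
#' C, all three are one clone). Identical chains observed in different
#' patients are treated as convergent recombination, never merged.
#'
#' @param tcr TCR chain table ([readTcrTable()] shape).
#' @param cells per-cell metadata table (or SingleCellExperiment) providing
#'   `cell_id` and `patient`; every TCR cell must appear here.
#' @param use_aa match on amino-acid CDR3 instead of nucleotide (default
#'   FALSE).
#' @param include_nonproductive also use non-productive chains (default
#'   FALSE: only productive chains define antigen specificity).
#' @return A [ClonePartition-class]. Cells in `cells` with no usable chain
#'   are reported in `unassignedCells()`. Clone ids are
#'   `<patient>_c<index>`, indexed by decreasing size then first cell id.
#' @export
assignClones <- function(tcr, cells, use_aa = FALSE,
                         include_nonproductive = FALSE) {
  tcr <- validateTcrTable(as.data.frame(tcr))
  cdf <- get_cell_table(cells)
  if (!all(c("cell_id", "patient") %in% names(cdf)))
    stopf("cell table must provide cell_id and patient columns")
  absent <- setdiff(unique(tcr$cell_id), cdf$cell_id)
  if (length(absent))
    stopf("TCR cell(s) absent from the cell table: %s",
          paste(head(absent, 5), collapse = ", "))
  if (!include_nonproductive) tcr <- tcr[tcr$productive, , drop = FALSE]
  cdr3 <- if (use_aa) tcr$cdr3_aa else tcr$cdr3_nt
  patient <- cdf$patient[match(tcr$cell_id, cdf$cell_id)]
  # chain identity key, per patient so clones never span patients
  key <- paste(patient, tcr$locus, tcr$v_gene, tcr$j_gene, cdr3, sep = "\r")

  with_chain <- unique(tcr$cell_id)
  unassigned <- setdiff(cdf$cell_id, with_chain)

  if (length(with_chain)) {
    # bipartite cell--chain graph; components restricted to cell vertices
    g <- igraph::graph_from_data_frame(
      data.frame(from = paste0("cell:", tcr$cell_id),
                 to = paste0("chain:", key)), directed = FALSE)
    comp <- igraph::components(g)$membership
    cellv <- grep("^cell:", names(comp), value = TRUE)
    member <- comp[cellv]
    ids <- sub("^cell:", "", cellv)
    groups <- split(ids, member)
    groups <- lapply(groups, sort)
    # deterministic clone naming: per patient, by decreasing size then
    # lexicographically first member
    gpat <- vapply(groups, function(g)
      cdf$patient[match(g[1], cdf$cell_id)], character(1))
    ord <- order(gpat, -lengths(groups),
                 vapply(groups, `[`, character(1), 1), method = "radix")
    groups <- groups[ord]; gpat <- gpat[ord]
    idx <- stats::ave(seq_along(gpat), gpat, FUN = seq_along)
    clone_id <- sprintf("%s_c%03d", gpat, idx)
    assignment <- setNames(rep(clone_id, lengths(groups)),
                           unlist(groups, use.names = FALSE))
    clones <- S4Vectors::DataFrame(clone_id = clone_id, patient = gpat,
                                   size = lengths(groups, use.names = FALSE))
  } else {
    assignment <- setNames(character(), character())
    clones <- S4Vectors::DataFrame(clone_id = character(),
                                   patient = character(), size = integer())
  }
  new("ClonePartition", assignment = assignment, clones = clones,
      unassigned = unassigned)
}

#' Summarize a clone partition
#'
#' @param partition a [ClonePartition-class].
#' @param cells cell metadata with `cell_id` and (optionally)
#'   `tetramer_label` for the per-clone tetramer composition.
#' @return List with `per_clone` (data.frame: clone_id, patient, size,
#'   n_tet_pos, n_tet_neg) and `global` (named list: n_expanded_clones,
#'   n_cells_expanded, n_singletons, n_unassigned).
#' @export
cloneSummary <- function(partition, cells = NULL) {
  cl <- as.data.frame(cloneTable(partition))
  a <- cloneAssignment(partition)
  if (!is.null(cells)) {
    cdf <- get_cell_table(cells)
    if ("tetramer_label" %in% names(cdf)) {
      lab <- setNames(as.character(cdf$tetramer_label), cdf$cell_id)
      pos <- tapply(lab[names(a)] == "positive", a, sum)
      cl$n_tet_pos <- as.integer(pos[cl$clone_id])
      cl$n_tet_neg <- cl$size - cl$n_tet_pos
    }
  }
  list(per_clone = cl,
       global = list(
         n_expanded_clones = sum(cl$size >= 2),
         n_cells_expanded = sum(cl$size[cl$size >= 2]),
         n_singletons = sum(cl$size == 1),
         n_unassigned = length(unassignedCells(partition))))
}
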