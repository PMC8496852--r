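#' Enumerate all intra-clone cell pairs
#'
#' All unordered pairs of eligible cells belonging to the same clonotype,
#' from clones with at least two eligible members. Eligibility is
#' typically "passed QC and has at least one reconstructed chain", which
#' is exactly the assigned-cell set of the partition intersected with the
#' QC-passing cells.
#'
#' @param partition a [ClonePartition-class].
#' @param eligible character vector of eligible cell ids (default: all
#'   assigned cells).
#' @return data.frame with columns cell_a, cell_b (cell_a < cell_b),
#'   patient, origin = "intra_clone".
#' @export
enumerateIntraPairs <- function(partition, eligible = NULL) {
  a <- cloneAssignment(partition)
  if (!is.null(eligible)) a <- a[names(a) %in% eligible]
  cl <- as.data.frame(cloneTable(partition))
  pat <- setNames(cl$patient, cl$clone_id)
  groups <- split(names(a), a)
  groups <- groups[lengths(groups) >= 2L]
  if (!length(groups)) {
    return(data.frame(cell_a = character(), cell_b = character(),
                      patient = character(), origin = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(names(groups), function(cid) {
    mem <- sort(groups[[cid]])
    idx <- utils::combn(length(mem), 2L)
    data.frame(cell_a = mem[idx[1, ]], cell_b = mem[idx[2, ]],
               patient = pat[[cid]], origin = "intra_clone",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample the size-matched random-clone pair set
#'
#' For each patient, draws as many random unordered pairs of eligible
#' tetramer-positive cells as that patient contributed intra-clone pairs.
#' Pairs whose two members belong to the same clonotype, and duplicates of
#' pairs already drawn, are rejected and redrawn (both exclusions can be
#' switched off to reproduce an uncorrected null). Seeded and
#' deterministic.
#'
#' @param intra_pairs output of [enumerateIntraPairs()].
#' @param cells cell metadata (cell_id, patient, tetramer_label).
#' @param partition the [ClonePartition-class] used for the intra pairs.
#' @param eligible character vector of eligible cell ids (QC-passing with
#'   at least one chain); random pairs are drawn from its
#'   tetramer-positive subset.
#' @param seed RNG seed.
#' @param exclude_intra reject pairs of clone-mates (default TRUE).
#' @param exclude_duplicates reject already-drawn pairs (default TRUE).
#' @param max_tries rejection-loop bound per patient before erroring.
#' @return data.frame in the same shape as `intra_pairs` with origin =
#'   "random_clone".
#' @export
sampleRandomPairs <- function(intra_pairs, cells, partition, eligible,
                              seed = 1, exclude_intra = TRUE,
                              exclude_duplicates = TRUE, max_tries = 10000) {
  cdf <- get_cell_table(cells)
  a <- cloneAssignment(partition)
  need <- table(intra_pairs$patient)
  pool_all <- cdf$cell_id[cdf$tetramer_label == "positive" &
                            cdf$cell_id %in% eligible]
  with_seed(seed, {
    out <- lapply(names(need), function(p) {
      pool <- sort(pool_all[cdf$patient[match(pool_all, cdf$cell_id)] == p])
      n <- as.integer(need[[p]])
      if (length(pool) < 2L)
        stopf("patient '%s' has %d eligible tetramer-positive cell(s); cannot draw pairs",
              p, length(pool))
      drawn <- character(0)
      res <- vector("list", n)
      k <- 0L; tries <- 0L
      while (k < n) {
        tries <- tries + 1L
        if (tries > max_tries)
          stopf("rejection sampling for patient '%s' exceeded %d tries; %d of %d pairs drawn (pool %d cells)",
                p, max_tries, k, n, length(pool))
        pr <- sort(pool[sample.int(length(pool), 2L)])
        key <- paste(pr, collapse = "\r")
        if (exclude_intra) {
          ca <- a[pr[1]]; cb <- a[pr[2]]
          if (!is.na(ca) && !is.na(cb) && ca == cb) next
        }
        if (exclude_duplicates && key %in% drawn) next
        drawn <- c(drawn, key)
        k <- k + 1L
        res[[k]] <- pr
      }
      m <- do.call(rbind, res)
      data.frame(cell_a = m[, 1], cell_b = m[, 2], patient = p,
                 origin = "random_clone", stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Pearson correlation of expression for each cell pair
#'
#' Correlates the two cells of each pair over all retained genes whose
#' annotation lacks the TR flag (T-cell receptor locus genes are excluded
#' because clone-mates share them by construction). TR genes are
#' identified by the `category` column of the annotation when provided,
#' otherwise by the symbol pattern `^TR[ABGD][VDJC]`; an explicit
#' `tr_genes` list overrides both.
#'
#' @param pairs data.frame with cell_a, cell_b (and any other columns,
#'   carried through).
#' @param x SingleCellExperiment or matrix; `layer` selects the assay
#'   (default "lognorm", the pre-scaling layer).
#' @param annotation optional data.frame with gene_id and category (or
#'   symbol) columns; defaults to the experiment's rowData.
#' @param tr_genes optional explicit character vector of TR gene ids.
#' @param layer expression layer.
#' @return The input pairs with an added `r` column; pairs where either
#'   cell has zero variance after TR exclusion are dropped with a warning.
#' @export
pairCorrelations <- function(pairs, x, annotation = NULL, tr_genes = NULL,
                             layer = "lognorm") {
  m <- get_layer(x, layer)
  if (is.null(tr_genes)) {
    if (is.null(annotation) && is(x, "SummarizedExperiment")) {
      rd <- as.data.frame(SummarizedExperiment::rowData(x))
      if (ncol(rd)) annotation <- cbind(gene_id = rownames(x), rd)
    }
    tr_genes <- find_tr_genes(rownames(m), annotation)
  }
  keep <- !(rownames(m) %in% tr_genes)
  if (!any(keep)) stopf("no genes left after TR exclusion")
  m <- m[keep, , drop = FALSE]
  missing <- setdiff(unique(c(pairs$cell_a, pairs$cell_b)), colnames(m))
  if (length(missing))
    stopf("pair member(s) absent from the expression layer: %s",
          paste(head(missing, 5), collapse = ", "))
  va <- m[, pairs$cell_a, drop = FALSE]
  vb <- m[, pairs$cell_b, drop = FALSE]
  sda <- apply(va, 2L, sd); sdb <- apply(vb, 2L, sd)
  ok <- sda > 0 & sdb > 0
  if (any(!ok))
    warnf("%d pair(s) dropped: zero-variance cell after TR exclusion",
          sum(!ok))
  r <- rep(NA_real_, nrow(pairs))
  r[ok] <- vapply(which(ok), function(i) cor(va[, i], vb[, i]),
                  numeric(1))
  out <- pairs[ok, , drop = FALSE]
  out$r <- r[ok]
  rownames(out) <- NULL
  out
}

# TR gene identification: annotation category flag if present, else the
# locus-symbol pattern.
find_tr_genes <- function(gene_ids, annotation = NULL) {
  if (!is.null(annotation) && "category" %in% names(annotation)) {
    return(annotation$gene_id[annotation$category == "TR"])
  }
  sym <- gene_ids
  if (!is.null(annotation) && "symbol" %in% names(annotation))
    sym <- annotation$symbol[match(gene_ids, annotation$gene_id)]
  gene_ids[grepl("^TR[ABGD][VDJC]", sym)]
}

#' Welch two-sample t-test on pair correlations
#'
#' Tests whether intra-clone correlations equal random-clone correlations:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p value.
#'
#' @param intra,random numeric vectors of correlations (>= 2 values each).
#' @return A [PairTestResult-class].
#' @export
welchTest <- function(intra, random) {
  if (length(intra) < 2L || length(random) < 2L)
    stopf("Welch test needs at least 2 values per side (got %d and %d)",
          length(intra), length(random))
  tt <- t.test(intra, random, var.equal = FALSE,
               alternative = "two.sided")
  new("PairTestResult",
      correlations_intra = as.numeric(intra),
      correlations_random = as.numeric(random),
      statistic = unname(tt$statistic),
      df = unname(tt$parameter),
      p_value = tt$p.value)
}

#' Clonal transcriptome-similarity test, end to end
#'
#' Builds the intra-clone pair set from the partition, samples the
#' size-matched random-clone null from the same patients' eligible
#' tetramer-positive cells, computes TR-excluded Pearson correlations on
#' the chosen layer for both sets, and compares them with the Welch
#' two-sample t-test. Pairs that share a cell are counted and reported
#' since they make the pair observations non-independent.
#'
#' @param sce normalized SingleCellExperiment restricted to QC-passing
#'   cells.
#' @param partition a [ClonePartition-class].
#' @param seed RNG seed for the random-pair draw.
#' @param layer expression layer for the correlations (default "lognorm").
#' @param eligible eligible cell ids; default: assigned cells present in
#'   the experiment.
#' @param ... passed to [sampleRandomPairs()].
#' @return List with `result` (a [PairTestResult-class]), `pairs` (the
#'   combined annotated pair table with correlations) and
#'   `n_shared_cell_pairs` (pairs sharing a member within each origin).
#' @export
cloneSimilarityTest <- function(sce, partition, seed = 1, layer = "lognorm",
                                eligible = NULL, ...) {
  if (is.null(eligible))
    eligible <- intersect(names(cloneAssignment(partition)), colnames(sce))
  intra <- enumerateIntraPairs(partition, eligible)
  if (!nrow(intra))
    stopf("no expanded clones among eligible cells; nothing to test")
  rnd <- sampleRandomPairs(intra, sce, partition, eligible, seed = seed, ...)
  pairs <- rbind(intra, rnd)
  pairs <- pairCorrelations(pairs, sce, layer = layer)
  res <- welchTest(pairs$r[pairs$origin == "intra_clone"],
                   pairs$r[pairs$origin == "random_clone"])
  shared <- vapply(split(pairs, pairs$origin), function(df) {
    sum(duplicated(c(df$cell_a, df$cell_b)))
  }, numeric(1))
  list(result = res, pairs = pairs, n_shared_cell_pairs = shared)
}
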