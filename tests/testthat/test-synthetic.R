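test_that("generation is deterministic given the seed", {
  d1 <- small_dataset(seed = 11)
  d2 <- small_dataset(seed = 11)
  expect_identical(as.matrix(SummarizedExperiment::assay(d1$sce)),
                   as.matrix(SummarizedExperiment::assay(d2$sce)))
  expect_identical(d1$tcr, d2$tcr)
  expect_identical(d1$truth, d2$truth)
  d3 <- small_dataset(seed = 12)
  expect_false(identical(as.matrix(SummarizedExperiment::assay(d1$sce)),
                         as.matrix(SummarizedExperiment::assay(d3$sce))))
})

test_that("planted clones share identical chains and chains are injective across clones", {
  ds <- small_dataset(seed = 21,
                      clone_size_distribution = data.frame(size = 3, count = 1))
  truth <- ds$truth$clone_assignment
  expect_equal(sort(as.vector(table(truth))), c(3, 3))  # one clone of 3 per patient
  key <- with(ds$tcr, paste(locus, v_gene, j_gene, cdr3_nt))
  for (cl in unique(truth)) {
    members <- names(truth)[truth == cl]
    keys <- lapply(members, function(cell) sort(key[ds$tcr$cell_id == cell]))
    expect_true(all(vapply(keys, identical, logical(1), keys[[1]])))
  }
  # no chain appears in two different clones or in any non-clone cell
  clone_cells <- names(truth)
  clone_keys <- key[ds$tcr$cell_id %in% clone_cells]
  other_keys <- key[!ds$tcr$cell_id %in% clone_cells]
  expect_length(intersect(unique(clone_keys), unique(other_keys)), 0)
  in_clone <- ds$tcr$cell_id %in% clone_cells
  by_clone <- lapply(split(key[in_clone], truth[ds$tcr$cell_id[in_clone]]),
                     unique)
  if (length(by_clone) > 1)
    expect_length(intersect(by_clone[[1]], by_clone[[2]]), 0)
})

test_that("CDR3 nucleotide sequences are in-frame, stop-free and consistent with the reported protein", {
  ds <- small_dataset(seed = 31)
  expect_true(all(nchar(ds$tcr$cdr3_nt) %% 3 == 0))
  expect_true(all(nchar(ds$tcr$cdr3_nt) >= 30 & nchar(ds$tcr$cdr3_nt) <= 45))
  expect_false(any(grepl("\\*", ds$tcr$cdr3_aa)))
  expect_equal(nchar(ds$tcr$cdr3_aa) * 3, nchar(ds$tcr$cdr3_nt))
})

test_that("the group effect doubles mean counts of planted genes at log2fc = 1", {
  # Monte-Carlo check of the generator against its own stated model:
  # with dropout disabled, planted genes should average ~2x in positive cells
  ds <- generateDataset(simConfig(
    n_patients = 1, cells_per_patient = 1000,
    fraction_tetramer_positive = 0.5,
    n_genes = 600, n_tr_genes = 20, n_mt_genes = 5, n_ribo_genes = 10,
    group_effect_genes = 100, group_log2fc = 1,
    clone_size_distribution = integer(0), clone_effect_genes = 0,
    dropout_logit_intercept = -30, dropout_logit_slope = 0,
    qc_violation_fraction = 0, seed = 41))
  m <- as.matrix(SummarizedExperiment::assay(ds$sce))
  pos <- SummarizedExperiment::colData(ds$sce)$tetramer_label == "positive"
  planted <- ds$truth$de_genes$gene
  ratio <- rowMeans(m[planted, pos]) / rowMeans(m[planted, !pos])
  expect_gt(mean(ratio), 1.8)
  expect_lt(mean(ratio), 2.2)
  # unplanted ordinary genes are not shifted
  other <- setdiff(rownames(m)[SummarizedExperiment::rowData(ds$sce)$category ==
                                 "OTHER"], planted)
  ratio0 <- rowMeans(m[other, pos]) / rowMeans(m[other, !pos])
  expect_lt(abs(mean(ratio0, na.rm = TRUE) - 1), 0.1)
})

test_that("with all effects zero the two sorted groups are exchangeable", {
  ds <- generateDataset(simConfig(
    n_patients = 1, cells_per_patient = 200,
    n_genes = 2000, n_tr_genes = 40, n_mt_genes = 10, n_ribo_genes = 20,
    group_effect_genes = 0, group_log2fc = 0,
    clone_size_distribution = integer(0), clone_effect_genes = 0,
    qc_violation_fraction = 0, seed = 51))
  ln <- log1p(as.matrix(SummarizedExperiment::assay(ds$sce)))
  ln <- ln[rowSums(ln > 0) >= 10, ]
  g1 <- SummarizedExperiment::colData(ds$sce)$tetramer_label == "positive"
  pv <- apply(ln, 1, function(v)
    suppressWarnings(wilcox.test(v[g1], v[!g1])$p.value))
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("QC violators break exactly one criterion each and config errors are caught", {
  ds <- small_dataset(seed = 61)
  flags <- filterCells(ds$sce, small_thresholds())$flags
  viol <- ds$truth$qc_should_fail
  expect_equal(sort(rownames(flags)[rowSums(flags) > 0]), sort(viol$cell_id))
  expect_true(all(rowSums(flags[viol$cell_id, , drop = FALSE]) == 1))
  for (i in seq_len(nrow(viol)))
    expect_true(flags[viol$cell_id[i], viol$rule[i]])
  # infeasible clone structure is refused up front
  expect_error(simConfig(cells_per_patient = 10,
                         clone_size_distribution = rep(4, 5)),
               "exceed")
})

test_that("fixtures round trip and tampering is detected", {
  ds <- small_dataset(seed = 71)
  dir <- withr::local_tempdir()
  writeFixture(ds, dir)
  expect_true(verifyFixture(dir))
  back <- readExpressionMatrix(file.path(dir, "counts.mtx"),
                               genes = file.path(dir, "counts.genes.txt"),
                               cells = file.path(dir, "counts.cells.txt"))
  expect_identical(as.matrix(SummarizedExperiment::assay(back)),
                   as.matrix(SummarizedExperiment::assay(ds$sce)))
  tcr_back <- readTcrTable(file.path(dir, "tcr_chains.tsv"))
  expect_identical(tcr_back$cdr3_nt, ds$tcr$cdr3_nt)
  # tamper
  cat("tampered\n", file = file.path(dir, "truth_qc.tsv"), append = TRUE)
  expect_error(verifyFixture(dir), "truth_qc.tsv")
  # refuse empty dataset
  empty <- ds; empty$sce <- ds$sce[, 0]
  expect_error(writeFixture(empty, dir), "empty")
})
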