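chain_row <- function(cell, locus = "TRB", v = "TRBV7", j = "TRBJ1",
                      nt = "TGTGCCAGC", aa = "CAS", productive = TRUE) {
  data.frame(cell_id = cell, locus = locus, v_gene = v, j_gene = j,
             cdr3_nt = nt, cdr3_aa = aa, productive = productive,
             stringsAsFactors = FALSE)
}

cells_tab <- function(ids, patient = "P1") {
  data.frame(cell_id = ids, patient = patient,
             tetramer_label = "positive", stringsAsFactors = FALSE)
}

test_that("cells sharing one chain join one clone; transitive closure holds", {
  tcr <- rbind(
    chain_row("A", nt = "AAATTT"), chain_row("B", nt = "AAATTT"),
    chain_row("B", locus = "TRA", v = "TRAV1", j = "TRAJ2", nt = "CCCGGG"),
    chain_row("C", locus = "TRA", v = "TRAV1", j = "TRAJ2", nt = "CCCGGG"),
    chain_row("D", nt = "GGGCCC"))
  part <- assignClones(tcr, cells_tab(c("A", "B", "C", "D")))
  a <- cloneAssignment(part)
  expect_equal(a[["A"]], a[["B"]])
  expect_equal(a[["B"]], a[["C"]])  # via B's alpha chain
  expect_false(a[["D"]] == a[["A"]])
  expect_equal(unname(sort(cloneSizes(part), decreasing = TRUE)), c(3, 1))
})

test_that("identical chains in different patients stay distinct clones", {
  tcr <- rbind(chain_row("A"), chain_row("B"))
  cells <- rbind(cells_tab("A", "P1"), cells_tab("B", "P2"))
  part <- assignClones(tcr, cells)
  a <- cloneAssignment(part)
  expect_false(a[["A"]] == a[["B"]])
  expect_equal(length(part), 2)
})

test_that("chain identity uses V, J and nucleotide CDR3; aa mode is looser", {
  # same aa CDR3 via synonymous codons, different nt
  tcr <- rbind(chain_row("A", nt = "TGTGCA", aa = "CA"),
               chain_row("B", nt = "TGCGCC", aa = "CA"))
  cells <- cells_tab(c("A", "B"))
  nt_part <- assignClones(tcr, cells)
  expect_false(cloneAssignment(nt_part)[["A"]] ==
                 cloneAssignment(nt_part)[["B"]])
  aa_part <- assignClones(tcr, cells, use_aa = TRUE)
  expect_equal(cloneAssignment(aa_part)[["A"]],
               cloneAssignment(aa_part)[["B"]])
  # different V gene blocks merging even with equal CDR3
  tcr2 <- rbind(chain_row("A"), chain_row("B", v = "TRBV9"))
  part2 <- assignClones(tcr2, cells)
  expect_equal(length(part2), 2)
})

test_that("non-productive chains are ignored by default but usable by flag", {
  tcr <- rbind(chain_row("A", productive = FALSE),
               chain_row("B", productive = FALSE),
               chain_row("B", nt = "TTTAAA"))
  cells <- cells_tab(c("A", "B"))
  part <- assignClones(tcr, cells)
  expect_true("A" %in% unassignedCells(part))
  expect_equal(names(cloneAssignment(part)), "B")
  part2 <- assignClones(tcr, cells, include_nonproductive = TRUE)
  expect_equal(cloneAssignment(part2)[["A"]], cloneAssignment(part2)[["B"]])
})

test_that("a never-seen chain adds exactly one singleton", {
  tcr <- rbind(chain_row("A", nt = "AAATTT"), chain_row("B", nt = "AAATTT"))
  part1 <- assignClones(tcr, cells_tab(c("A", "B")))
  tcr2 <- rbind(tcr, chain_row("C", nt = "CGTACG"))
  part2 <- assignClones(tcr2, cells_tab(c("A", "B", "C")))
  s1 <- sum(cloneSizes(part1) == 1)
  s2 <- sum(cloneSizes(part2) == 1)
  expect_equal(s2, s1 + 1)
  expect_error(assignClones(tcr2, cells_tab(c("A", "B"))), "absent")
})

test_that("planted clones are recovered exactly on synthetic data", {
  ds <- small_dataset(seed = 141)
  part <- assignClones(ds$tcr, ds$sce)
  truth <- ds$truth$clone_assignment
  a <- cloneAssignment(part)
  # every truth clone maps to exactly one recovered clone of the same cells
  recovered_groups <- split(names(a), a)
  truth_groups <- split(names(truth), truth)
  match_keys <- function(gs) sort(vapply(gs, function(g)
    paste(sort(g), collapse = "|"), character(1)))
  expect_true(all(match_keys(truth_groups) %in% match_keys(recovered_groups)))
  # partition property: disjoint cover, sizes sum correctly
  expect_equal(sum(cloneSizes(part)), length(a))
  expect_false(anyDuplicated(names(a)) > 0)
  # summary agrees with ground truth counts
  summ <- cloneSummary(part, ds$sce)
  truth_sizes <- table(truth)
  expect_equal(summ$global$n_expanded_clones,
               sum(truth_sizes >= 2))
  expect_equal(summ$global$n_cells_expanded, sum(truth_sizes[truth_sizes >= 2]))
})

test_that("clone summary composes sizes and tetramer composition", {
  tcr <- rbind(chain_row("A", nt = "A1"), chain_row("B", nt = "A1"),
               chain_row("C", nt = "A1"),
               chain_row("D", nt = "B1"), chain_row("E", nt = "B1"),
               chain_row("F", nt = "C1"), chain_row("G", nt = "D1"))
  cells <- cells_tab(LETTERS[1:7])
  cells$tetramer_label[7] <- "negative"
  summ <- cloneSummary(assignClones(tcr, cells), cells)
  expect_equal(summ$global$n_expanded_clones, 2)
  expect_equal(summ$global$n_cells_expanded, 5)
  expect_equal(summ$global$n_singletons, 2)
  expect_equal(sum(summ$per_clone$n_tet_neg), 1)
})
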