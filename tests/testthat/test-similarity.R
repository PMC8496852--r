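toy_partition <- function(sizes, patient = "P1") {
  cells <- sprintf("%s_c%02d", patient, seq_len(sum(sizes) + 4))
  a <- setNames(rep(sprintf("%s_k%d", patient, seq_along(sizes)), sizes),
                cells[seq_len(sum(sizes))])
  clones <- S4Vectors::DataFrame(clone_id = sprintf("%s_k%d", patient,
                                                    seq_along(sizes)),
                                 patient = patient, size = as.integer(sizes))
  new("ClonePartition", assignment = a, clones = clones,
      unassigned = character())
}

test_that("intra-clone pair enumeration is n-choose-2 per clone", {
  p <- toy_partition(c(3, 2))
  pairs <- enumerateIntraPairs(p)
  expect_equal(nrow(pairs), 3 + 1)
  expect_true(all(pairs$cell_a < pairs$cell_b))
  expect_true(all(pairs$origin == "intra_clone"))
  # combinatorial oracle for sizes up to 10
  for (n in 2:10) {
    expect_equal(nrow(enumerateIntraPairs(toy_partition(n))), choose(n, 2))
  }
  # no expanded clones -> empty set
  expect_equal(nrow(enumerateIntraPairs(toy_partition(c(1, 1)))), 0)
  # eligibility restriction shrinks clones before pairing
  pairs2 <- enumerateIntraPairs(toy_partition(4),
                                eligible = c("P1_c01", "P1_c02"))
  expect_equal(nrow(pairs2), 1)
})

test_that("random pairs are size-matched per patient, seeded, and respect exclusions", {
  ds <- small_dataset(seed = 151)
  sce <- prep_sce(ds)
  part <- assignClones(ds$tcr[ds$tcr$cell_id %in% colnames(sce), ], sce)
  eligible <- intersect(names(cloneAssignment(part)), colnames(sce))
  intra <- enumerateIntraPairs(part, eligible)
  rnd <- sampleRandomPairs(intra, sce, part, eligible, seed = 5)
  expect_equal(nrow(rnd), nrow(intra))
  expect_equal(table(rnd$patient), table(intra$patient))
  # determinism
  rnd2 <- sampleRandomPairs(intra, sce, part, eligible, seed = 5)
  expect_identical(rnd, rnd2)
  # all members tetramer-positive and eligible
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  mem <- unique(c(rnd$cell_a, rnd$cell_b))
  expect_true(all(cd[mem, "tetramer_label"] == "positive"))
  expect_true(all(mem %in% eligible))
  # no clone-mate pairs, no duplicates
  a <- cloneAssignment(part)
  same <- !is.na(a[rnd$cell_a]) & !is.na(a[rnd$cell_b]) &
    a[rnd$cell_a] == a[rnd$cell_b]
  expect_false(any(same))
  expect_false(any(duplicated(paste(rnd$cell_a, rnd$cell_b))))
  # infeasible pools error
  tiny <- data.frame(cell_id = c("x1", "x2"), patient = "P9",
                     tetramer_label = c("positive", "negative"))
  expect_error(
    sampleRandomPairs(data.frame(cell_a = "x1", cell_b = "x2",
                                 patient = "P9", origin = "intra_clone"),
                      tiny, part, c("x1", "x2"), seed = 1),
    "eligible")
})

test_that("pair correlations exclude TR genes entirely", {
  set.seed(30)
  genes <- c("TRAV1", "TRBV5", "TRBJ2", paste0("G", 1:50))
  m <- matrix(rnorm(53 * 4, 5), 53, 4,
              dimnames = list(genes, paste0("c", 1:4)))
  pairs <- data.frame(cell_a = c("c1", "c3"), cell_b = c("c2", "c4"),
                      stringsAsFactors = FALSE)
  base <- pairCorrelations(pairs, m)
  # two cells identical on non-TR genes, wild on TR genes -> r = 1
  m2 <- m
  m2[, "c2"] <- m[, "c1"]
  m2[1:3, "c2"] <- c(100, -50, 7)
  expect_equal(pairCorrelations(pairs[1, ], m2)$r, 1)
  # perturbing TR genes never changes any correlation
  m3 <- m
  m3[1:3, ] <- matrix(rnorm(12, 100, 50), 3)
  expect_equal(pairCorrelations(pairs, m3)$r, base$r)
  # perfect linear cases on a 5-gene toy
  toy <- cbind(a = 1:5, b = 2 * (1:5), c = 10 - 2 * (1:5))
  rownames(toy) <- paste0("G", 1:5)
  tp <- data.frame(cell_a = c("a", "a"), cell_b = c("b", "c"))
  expect_equal(pairCorrelations(tp, toy)$r, c(1, -1))
  # zero-variance cell dropped with warning
  zv <- cbind(a = rep(1, 5), b = rnorm(5))
  rownames(zv) <- paste0("G", 1:5)
  expect_warning(
    out <- pairCorrelations(data.frame(cell_a = "a", cell_b = "b"), zv),
    "zero-variance")
  expect_equal(nrow(out), 0)
})

test_that("welch test matches the closed-form oracle on randomized samples", {
  r <- welchTest(c(0.5, 0.6, 0.7), c(0.1, 0.2, 0.3))
  o <- welch_oracle(c(0.5, 0.6, 0.7), c(0.1, 0.2, 0.3))
  expect_equal(r@statistic, o$t, tolerance = 1e-8)
  expect_equal(r@df, o$df, tolerance = 1e-8)
  expect_equal(r@p_value, o$p, tolerance = 1e-8)
  set.seed(31)
  for (i in 1:20) {
    x <- runif(sample(3:30, 1), -1, 1)
    y <- runif(sample(3:30, 1), -1, 1)
    got <- welchTest(x, y)
    want <- welch_oracle(x, y)
    expect_equal(got@statistic, want$t, tolerance = 1e-8)
    expect_equal(got@df, want$df, tolerance = 1e-8)
    expect_equal(got@p_value, want$p, tolerance = 1e-8)
    swapped <- welchTest(y, x)
    expect_equal(swapped@statistic, -got@statistic)
    expect_equal(swapped@p_value, got@p_value)
  }
  same <- c(0.1, 0.2, 0.3)
  id <- welchTest(same, same)
  expect_equal(id@statistic, 0)
  expect_equal(id@p_value, 1)
  expect_error(welchTest(0.5, c(0.1, 0.2)), "at least 2")
})

test_that("clone effect raises intra-clone correlations end to end", {
  ds <- small_dataset(seed = 161, clone_effect_log2fc = 1.5,
                      clone_size_distribution = rep(4, 6))
  sce <- prep_sce(ds)
  part <- assignClones(ds$tcr[ds$tcr$cell_id %in% colnames(sce), ], sce)
  cs <- cloneSimilarityTest(sce, part, seed = 9)
  expect_lt(cs$result@p_value, 0.05)
  expect_gt(mean(cs$result@correlations_intra),
            mean(cs$result@correlations_random))
  expect_equal(length(cs$result@correlations_intra),
               length(cs$result@correlations_random))
})
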