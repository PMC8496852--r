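test_that("hurdle test degenerate cases", {
  # all-zero gene: no testable component, p = 1
  r <- hurdleTest(rep(0, 5), rep(0, 6))
  expect_equal(r$p_value, 1)
  expect_equal(r$df, 0L)
  # fully detected, identically distributed: both near-null
  set.seed(1)
  v <- rnorm(50, 5)
  r2 <- hurdleTest(v, v)
  expect_lt(r2$statistic, 1e-8)
  expect_gt(r2$p_value, 0.999)
  # fully detected -> discrete component omitted
  expect_true(is.na(r2$chisq_discrete))
  expect_equal(r2$df, 1L)
  expect_error(hurdleTest(1, c(1, 2)), "at least 2")
})

test_that("hurdle test picks up detection-rate and mean shifts", {
  set.seed(2)
  x <- c(rep(0, 40), rnorm(10, 2))   # 20% detected
  y <- c(rep(0, 10), rnorm(40, 2))   # 80% detected
  expect_lt(hurdleTest(x, y)$p_value, 1e-4)
  x2 <- rnorm(50, 1); y2 <- rnorm(50, 3)
  expect_lt(hurdleTest(x2, y2)$p_value, 1e-6)
})

test_that("average log2 fold change is antisymmetric and matches the toy case", {
  set.seed(3)
  x <- runif(20); y <- runif(20)
  expect_equal(avgLog2FC(x, y), -avgLog2FC(y, x))
  expect_equal(avgLog2FC(x, x), 0)
  # group means 3 and 1 on the linear scale, eps 1 -> log2(4/2) = 1
  x3 <- log(3 + 1)  # single value whose expm1 mean is 3
  y3 <- log(1 + 1)
  expect_equal(avgLog2FC(rep(x3, 4), rep(y3, 4)), 1)
})

test_that("runDE is antisymmetric under group swap and internally consistent", {
  ds <- small_dataset(seed = 111)
  sce <- prep_sce(ds)
  g <- SummarizedExperiment::colData(sce)$tetramer_label == "positive"
  de1 <- runDE(sce, g)
  de2 <- runDE(sce, !g)
  expect_equal(de1$p_value, de2$p_value)
  expect_equal(de1$log2fc, -de2$log2fc)
  expect_equal(de1$rank_score, -de2$rank_score)
  # BH consistency: fdr from p.adjust, monotone over ranked p
  expect_equal(de1$fdr, p.adjust(de1$p_value, "BH"))
  ord <- order(de1$p_value)
  expect_true(all(diff(cummin(rev(de1$fdr[ord]))) <= 1e-15))
  expect_true(all(de1$fdr >= de1$p_value - 1e-15))
  # rank_score sign follows log2fc
  nz <- de1$p_value < 1 & de1$log2fc != 0
  expect_true(all(sign(de1$rank_score[nz]) == sign(de1$log2fc[nz])))
})

test_that("DEG selection applies exact strict thresholds", {
  res <- S4Vectors::DataFrame(
    gene = c("a", "b", "c", "d"),
    log2fc = c(0.60, 0.58, 2.0, -0.9),
    p_value = c(1e-4, 1e-4, 0.02, 1e-5),
    fdr = c(0.04, 0.04, 0.06, 0.01))
  expect_setequal(selectDegs(res), c("a", "d"))
  # the exact threshold is log2(1.5) = 0.584962..., not the rounded 0.58
  res$log2fc[2] <- 0.5849
  expect_setequal(selectDegs(res), c("a", "d"))
  res$log2fc[2] <- 0.5850
  expect_setequal(selectDegs(res), c("a", "b", "d"))
  # the rounded display threshold remains selectable
  expect_setequal(selectDegs(res, min_abs_fc = 2^0.58), c("a", "b", "d"))
})

test_that("the ranking metric is sign times log10 p with deterministic ties", {
  res <- S4Vectors::DataFrame(
    gene = c("up", "dn", "tie_b", "tie_a", "null"),
    log2fc = c(2, -1, 1, 1, 0),
    p_value = c(0.001, 0.01, 0.1, 0.1, 0.5))
  r <- rankMetric(res)
  expect_equal(unname(r["up"]), 3)
  expect_equal(unname(r["dn"]), -2)
  expect_equal(unname(r["null"]), 0)
  # descending order, ties broken lexicographically
  expect_identical(names(r), c("up", "tie_a", "tie_b", "null", "dn"))
  # p = 0 is clamped, not infinite
  res$p_value[1] <- 0
  expect_warning(r0 <- rankMetric(res), "clamped")
  expect_equal(unname(r0["up"]), 300)
})

test_that("wilcoxon alternative runs and broadly agrees on strong signals", {
  ds <- small_dataset(seed = 121)
  sce <- prep_sce(ds)
  deh <- runDE(sce, "tetramer_label")
  dew <- runDE(sce, "tetramer_label", test = "wilcoxon")
  strong <- deh$gene[deh$fdr < 1e-4]
  expect_gt(length(strong), 0)
  expect_gt(mean(dew[strong, "fdr"] < 0.05), 0.8)
})
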