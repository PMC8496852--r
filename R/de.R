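#' Two-part (hurdle) test for one gene
#'
#' Covariate-free hurdle likelihood-ratio test in the style of single-cell
#' hurdle models: a discrete component compares detection rates
#' (value > 0) between the two groups by a binomial likelihood-ratio
#' chi-square (1 df), and a continuous component compares Gaussian models
#' of the positive values with and without a group mean difference
#' (1 df). The combined statistic is the sum of the available components
#' with matching degrees of freedom; a component is omitted when it is
#' degenerate (all cells detected, none detected, fewer than two positive
#' values overall, or positives confined to one group for the continuous
#' part).
#'
#' @param x,y numeric vectors of log-normalized expression for the two
#'   groups (at least 2 cells each).
#' @return List with `p_value`, `statistic`, `df`, and the per-component
#'   statistics `chisq_discrete`, `chisq_continuous` (NA when omitted).
#' @examples
#' hurdleTest(c(0, 0, 1.2, 2.1), c(0, 2.5, 3.1, 2.8))
#' @export
hurdleTest <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stopf("each group needs at least 2 cells (got %d and %d)",
          length(x), length(y))
  res <- hurdle_test_matrix(rbind(c(x, y)),
                            rep(c(TRUE, FALSE), c(length(x), length(y))))
  list(p_value = res$p_value, statistic = res$statistic, df = res$df,
       chisq_discrete = res$chisq_discrete,
       chisq_continuous = res$chisq_continuous)
}

# Vectorized hurdle LRT over the rows of a genes x cells matrix.
# g1 is a logical mask over columns selecting group 1.
hurdle_test_matrix <- function(m, g1) {
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
  det <- m > 0
  d1 <- rowSums(det[, g1, drop = FALSE])
  d2 <- rowSums(det[, !g1, drop = FALSE])
  d <- d1 + d2

  # --- discrete component: binomial LRT on detection rates ---
  bll <- function(dd, nn) {
    p <- dd / nn
    out <- numeric(length(dd))
    pos <- dd > 0
    out[pos] <- out[pos] + dd[pos] * log(p[pos])
    ltn <- dd < nn
    out[ltn] <- out[ltn] + (nn - dd[ltn]) * log(1 - p[ltn])
    out
  }
  disc_ok <- d > 0 & d < n
  chi_d <- rep(NA_real_, nrow(m))
  chi_d[disc_ok] <- 2 * (bll(d1[disc_ok], n1) + bll(d2[disc_ok], n2) -
                           bll(d[disc_ok], n))

  # --- continuous component: Gaussian LRT on positive values ---
  mp <- m
  mp[!det] <- 0
  s1 <- rowSums(mp[, g1, drop = FALSE]);  s2 <- rowSums(mp[, !g1, drop = FALSE])
  q1 <- rowSums(mp[, g1, drop = FALSE]^2); q2 <- rowSums(mp[, !g1, drop = FALSE]^2)
  mu1 <- ifelse(d1 > 0, s1 / d1, 0)
  mu2 <- ifelse(d2 > 0, s2 / d2, 0)
  mu0 <- ifelse(d > 0, (s1 + s2) / d, 0)
  rss1 <- pmax(q1 - d1 * mu1^2, 0) + pmax(q2 - d2 * mu2^2, 0)
  rss0 <- pmax(q1 + q2 - d * mu0^2, 0)
  cont_ok <- d >= 2 & d1 >= 1 & d2 >= 1
  chi_c <- rep(NA_real_, nrow(m))
  # guard: a perfect within-group fit (rss1 == 0) gives an unbounded LRT;
  # floor the ratio's denominator to keep the statistic finite
  ratio <- rss0 / pmax(rss1, rss0 * 1e-12)
  ratio[rss0 == 0] <- 1
  chi_c[cont_ok] <- d[cont_ok] * log(ratio[cont_ok])

  stat <- ifelse(is.na(chi_d), 0, chi_d) + ifelse(is.na(chi_c), 0, chi_c)
  df <- as.integer(!is.na(chi_d)) + as.integer(!is.na(chi_c))
  p <- rep(1, nrow(m))
  has <- df > 0
  p[has] <- pchisq(stat[has], df = df[has], lower.tail = FALSE)
  list(p_value = p, statistic = stat, df = df,
       chisq_discrete = chi_d, chisq_continuous = chi_c)
}

#' Average log2 fold change between two groups
#'
#' Seurat-style linear-scale definition: the group means of exp(x) - 1
#' (undoing the log1p-style transform), each offset by `eps`, entered into
#' log2. Antisymmetric under group swap.
#'
#' @param x,y log-normalized expression vectors for groups 1 and 2.
#' @param eps offset guarding against empty means (default 1).
#' @return log2 fold change (group 1 over group 2).
#' @export
avgLog2FC <- function(x, y, eps = 1) {
  log2((mean(expm1(x)) + eps) / (mean(expm1(y)) + eps))
}

#' Per-gene differential expression between two cell groups
#'
#' Runs the hurdle test (or a Wilcoxon rank-sum alternative) on every gene
#' of a log-normalized layer, computes the average log2 fold change and
#' detection fractions, adjusts p values by Benjamini-Hochberg, and
#' attaches the signed significance ranking score
#' `-sign(log2fc) * log10(p)` used for preranked enrichment (most
#' significantly up-regulated gene first).
#'
#' @param x SingleCellExperiment (with the chosen layer) or matrix.
#' @param group logical/two-level vector over cells, or the name of a
#'   colData column (e.g. "tetramer_label"); the first level / TRUE /
#'   "positive" is group 1.
#' @param layer assay to test (default "lognorm").
#' @param test "hurdle" (default) or "wilcoxon".
#' @param eps fold-change offset, see [avgLog2FC()].
#' @return A [S4Vectors::DataFrame] with one row per gene: gene, log2fc,
#'   p_value, fdr, pct_detected_group1, pct_detected_group2, rank_score;
#'   rows in input gene order.
#' @export
runDE <- function(x, group, layer = "lognorm", test = c("hurdle", "wilcoxon"),
                  eps = 1) {
  test <- match.arg(test)
  m <- get_layer(x, layer)
  if (length(group) == 1L && is.character(group)) {
    df <- get_cell_table(x)
    if (!group %in% names(df)) stopf("no colData column '%s'", group)
    group <- df[[group]]
  }
  g1 <- group_mask(group, ncol(m))
  if (sum(g1) < 2L || sum(!g1) < 2L)
    stopf("each group needs at least 2 cells")

  if (test == "hurdle") {
    ht <- hurdle_test_matrix(m, g1)
    p <- ht$p_value
  } else {
    p <- apply(m, 1L, function(v) {
      if (all(v[g1] == v[!g1][1]) && all(v == v[1])) return(1)
      suppressWarnings(wilcox.test(v[g1], v[!g1])$p.value)
    })
    p[is.na(p)] <- 1
  }
  mean1 <- rowMeans(expm1(m[, g1, drop = FALSE]))
  mean2 <- rowMeans(expm1(m[, !g1, drop = FALSE]))
  l2fc <- log2((mean1 + eps) / (mean2 + eps))
  res <- S4Vectors::DataFrame(
    gene = rownames(m),
    log2fc = l2fc,
    p_value = p,
    fdr = p.adjust(p, method = "BH"),
    pct_detected_group1 = rowMeans(m[, g1, drop = FALSE] > 0),
    pct_detected_group2 = rowMeans(m[, !g1, drop = FALSE] > 0)
  )
  res$rank_score <- rank_score(res$log2fc, res$p_value)
  rownames(res) <- res$gene
  res
}

group_mask <- function(group, n) {
  if (length(group) != n)
    stopf("group vector length (%d) must match cell count (%d)",
          length(group), n)
  if (is.logical(group)) return(group)
  lv <- unique(as.character(group))
  if (length(lv) != 2L)
    stopf("group must have exactly 2 levels (got: %s)",
          paste(lv, collapse = ", "))
  ref <- if ("positive" %in% lv) "positive" else sort(lv)[1]
  as.character(group) == ref
}

# Signed significance score: -sign(log2fc) * log10(p), p floored at 1e-300.
rank_score <- function(log2fc, p) {
  if (any(p <= 0)) {
    warnf("%d p-value(s) of 0 clamped to 1e-300 before log10", sum(p <= 0))
    p <- pmax(p, 1e-300)
  }
  -sign(log2fc) * log10(p)
}

#' Select differentially expressed genes
#'
#' Genes with FDR strictly below `fdr_max` and absolute average fold change
#' strictly above `min_abs_fc` (compared on the log2 scale against
#' `log2(min_abs_fc)`, the exact value, not its rounded display form).
#'
#' @param results output of [runDE()].
#' @param fdr_max FDR ceiling (default 0.05).
#' @param min_abs_fc linear fold-change floor (default 1.5).
#' @return Character vector of selected gene ids.
#' @export
selectDegs <- function(results, fdr_max = 0.05, min_abs_fc = 1.5) {
  results$gene[results$fdr < fdr_max &
                 abs(results$log2fc) > log2(min_abs_fc)]
}

#' Signed significance ranking for preranked enrichment
#'
#' Orders the full test result by `-sign(log2fc) * log10(p)` descending, so
#' the most significantly up-regulated gene is first and the most
#' significantly down-regulated gene is last. Genes with zero log2
#' fold change score 0; ties are broken by gene id (lexicographic) for
#' determinism.
#'
#' @param results output of [runDE()].
#' @return Named numeric vector of rank scores, sorted descending; names
#'   are gene ids.
#' @export
rankMetric <- function(results) {
  s <- rank_score(results$log2fc, results$p_value)
  names(s) <- results$gene
  ord <- order(-s, names(s), method = "radix")
  s[ord]
}
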