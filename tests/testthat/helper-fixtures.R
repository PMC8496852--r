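# Small simulation configurations and independent oracles shared across
# test files. All fixtures are generated in code; nothing is read from disk.

# A small but complete dataset: 2 patients, clones, violators, chains.
small_config <- function(seed = 101, ...) {
  args <- list(
    n_patients = 2, cells_per_patient = 80,
    fraction_tetramer_positive = 0.5,
    n_genes = 800, n_tr_genes = 40, n_mt_genes = 10, n_ribo_genes = 20,
    clone_size_distribution = data.frame(size = c(4, 3, 2), count = c(1, 1, 2)),
    clone_effect_genes = 100,
    qc_violation_fraction = 0.1, qc_min_genes = 300,
    seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simConfig, args)
}

# thresholds matched to the small config's 800-gene scale
small_thresholds <- function() {
  qcThresholds(min_genes = 300, max_genes = 800)
}

small_dataset <- function(seed = 101, ...) {
  generateDataset(small_config(seed = seed, ...))
}

# dataset -> QC'ed + normalized experiment
prep_sce <- function(ds, thresholds = small_thresholds()) {
  qc <- filterCells(ds$sce, thresholds)
  sce <- ds$sce[, qc$pass]
  sce <- sce[filterGenes(sce, thresholds), ]
  normalizeExpression(sce)
}

## ---- independent oracles ----

# Brute-force full-quantile normalization: explicit order-statistic means
# and per-rank assignment, no shared code with quantileNormalize().
qn_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    sv <- sort(v)
    for (i in seq_along(v)) {
      # positions this value's tie block occupies in the sorted vector
      span <- which(sv == v[i])
      out[i, j] <- mean(ref[span])
    }
  }
  out
}

# Exhaustive prefix-enumeration enrichment score: walks every prefix by
# explicit loop, then applies the stated extremum rule (positive extreme
# wins magnitude ties to 1e-9).
es_oracle <- function(scores, hit_mask, p = 1) {
  scores <- unname(scores)
  N <- length(scores)
  nh <- sum(hit_mask)
  denom <- sum(abs(scores[hit_mask])^p)
  run <- 0
  prefix <- numeric(N)
  for (i in seq_len(N)) {
    run <- run + if (hit_mask[i]) abs(scores[i])^p / denom else
      -1 / (N - nh)
    prefix[i] <- run
  }
  hi <- max(prefix); lo <- min(prefix)
  if (hi >= abs(lo) - 1e-9) hi else lo
}

# Closed-form Welch statistic and Satterthwaite df.
welch_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Exact two-sided Wilcoxon rank-sum p by complete enumeration of all
# C(n1+n2, n1) group assignments (tie-free inputs only).
wilcox_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- combn(length(pooled), n1)
  w_all <- apply(combs, 2, function(idx)
    sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  m <- n1 * length(y) / 2
  mean(abs(w_all - m) >= abs(w_obs - m) - 1e-9)
}
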