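#' Filter a gene-set collection against a ranked universe
#'
#' Each set is first intersected with the ranked gene universe; sets are
#' retained when the intersection size lies within `[min_size, max_size]`
#' (defaults 15 and 500, the bounds used to select testable pathways).
#'
#' @param sets named list of character vectors (e.g. from [readGmt()]).
#' @param universe character vector of ranked gene ids.
#' @param min_size,max_size inclusive size bounds after intersection.
#' @return Named list of intersected sets (file order preserved).
#' @export
filterSets <- function(sets, universe, min_size = 15, max_size = 500) {
  if (!length(universe)) stopf("ranked universe is empty")
  inter <- lapply(sets, function(s) s[s %in% universe])
  keep <- lengths(inter) >= min_size & lengths(inter) <= max_size
  inter[keep]
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list from top to bottom; at each gene in the set the
#' running sum increases by |r|^p / sum over hits of |r|^p, at each other
#' gene it decreases by 1/(N - |S|). The enrichment score is the signed
#' extremum of the running sum; the leading edge is the subset of hits at
#' or before a positive extremum (at or after, for a negative one).
#'
#' @param ranked named numeric vector of rank scores, sorted descending
#'   (ties already broken); names are gene ids.
#' @param set character vector of gene ids (subset of the universe after
#'   intersection; ids absent from `ranked` are ignored).
#' @param p weight exponent on |score| (default 1; 0 gives the unweighted
#'   Kolmogorov-Smirnov statistic).
#' @return List with `es`, `running` (the full running sum) and
#'   `leading_edge` (character vector of hit genes).
#' @examples
#' r <- c(g1 = 2, g2 = 1.5, g3 = 1, g4 = 0.5, g5 = 0.1)
#' enrichmentScore(r, c("g2", "g4"))$es  # 0.4167
#' @export
enrichmentScore <- function(ranked, set, p = 1) {
  hits <- names(ranked) %in% set
  es_running(ranked, hits, p, leading = TRUE)
}

# Core running-sum computation on a precomputed hit mask.
es_running <- function(scores, hits, p, leading = FALSE) {
  N <- length(scores)
  nh <- sum(hits)
  if (nh == 0L) stopf("gene set has no overlap with the ranked list")
  if (nh == N) {
    run <- cumsum(abs(scores)^p / sum(abs(scores)^p))
    le <- if (leading) seq_len(N) else NULL
    return(list(es = 1, running = run,
                leading_edge = if (leading) names(scores)[le]))
  }
  w <- abs(scores[hits])^p
  denom <- sum(w)
  if (denom == 0) stopf("degenerate weights: all hit scores are zero")
  steps <- numeric(N)
  steps[hits] <- w / denom
  steps[!hits] <- -1 / (N - nh)
  run <- cumsum(steps)
  # signed extremum; when the positive and negative extremes tie in
  # magnitude (to 1e-9), the positive one is taken, deterministically
  mx <- max(run); mn <- min(run)
  if (mx >= abs(mn) - 1e-9) {
    i <- which.max(run); es <- mx
  } else {
    i <- which.min(run); es <- mn
  }
  out <- list(es = es, running = run)
  if (leading) {
    idx <- which(hits)
    out$leading_edge <- if (es >= 0) names(scores)[idx[idx <= i]]
    else names(scores)[idx[idx >= i]]
  }
  out
}

#' Gene-tag permutation null for one set
#'
#' Permutes which positions of the ranked list are "hits" (`n_perm` times,
#' seeded), recomputes the enrichment score each time, and reports the
#' normalized enrichment score (observed ES divided by the mean |ES| of
#' same-sign permutations) and the one-sided permutation p value
#' `(1 + #{|ES_perm| >= |ES|, same sign}) / (1 + #{same sign})`.
#'
#' @inheritParams enrichmentScore
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return List with `es`, `nes`, `p_perm`, `n_same_sign`.
#' @export
permutationNull <- function(ranked, set, p = 1, n_perm = 1000, seed = 1) {
  if (n_perm < 100) stopf("n_perm must be at least 100 (got %d)", n_perm)
  scores <- as.numeric(ranked)
  hits <- names(ranked) %in% set
  nh <- sum(hits)
  es <- es_running(scores, hits, p)$es
  if (es == 0) return(list(es = 0, nes = 0, p_perm = 1, n_same_sign = 0L))
  N <- length(scores)
  es_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      mask <- logical(N)
      mask[sample.int(N, nh)] <- TRUE
      es_running(scores, mask, p)$es
    }, numeric(1))
  })
  same <- sign(es_perm) == sign(es)
  if (!any(same)) {
    warnf("no same-sign permutations; p set to 1 and NES left unscaled")
    return(list(es = es, nes = NA_real_, p_perm = 1, n_same_sign = 0L))
  }
  nes <- es / mean(abs(es_perm[same]))
  p_perm <- (1 + sum(abs(es_perm[same]) >= abs(es))) / (1 + sum(same))
  list(es = es, nes = nes, p_perm = p_perm, n_same_sign = sum(same))
}

#' Preranked gene-set enrichment over a collection
#'
#' Filters the collection by intersected size, scores every retained set
#' with the weighted running-sum statistic and a seeded gene-tag
#' permutation null, and adjusts the permutation p values by
#' Benjamini-Hochberg across the collection.
#'
#' @inheritParams permutationNull
#' @param sets named list of gene sets.
#' @param min_size,max_size size bounds after intersection with the ranked
#'   universe (defaults 15, 500).
#' @return [S4Vectors::DataFrame] with one row per retained set: set_name,
#'   size_after_filter, es, nes, p_perm, fdr, leading_edge (CharacterList).
#' @export
runGsea <- function(ranked, sets, min_size = 15, max_size = 500, p = 1,
                    n_perm = 1000, seed = 1) {
  fs <- filterSets(sets, names(ranked), min_size, max_size)
  if (!length(fs))
    return(S4Vectors::DataFrame(set_name = character(),
                                size_after_filter = integer(),
                                es = numeric(), nes = numeric(),
                                p_perm = numeric(), fdr = numeric()))
  rows <- lapply(seq_along(fs), function(i) {
    esr <- enrichmentScore(ranked, fs[[i]], p = p)
    pn <- permutationNull(ranked, fs[[i]], p = p, n_perm = n_perm,
                          seed = seed + i)
    list(es = esr$es, nes = pn$nes, p_perm = pn$p_perm,
         leading_edge = esr$leading_edge)
  })
  res <- S4Vectors::DataFrame(
    set_name = names(fs),
    size_after_filter = lengths(fs),
    es = vapply(rows, `[[`, numeric(1), "es"),
    nes = vapply(rows, `[[`, numeric(1), "nes"),
    p_perm = vapply(rows, `[[`, numeric(1), "p_perm")
  )
  res$fdr = p.adjust(res$p_perm, method = "BH")
  res$leading_edge <- S4Vectors::SimpleList(lapply(rows, `[[`, "leading_edge"))
  rownames(res) <- res$set_name
  res
}
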