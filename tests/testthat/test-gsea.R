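test_that("set filtering intersects with the universe before sizing", {
  universe <- paste0("G", 1:100)
  sets <- list(small = paste0("G", 1:14),          # 14 in universe
               exact = paste0("G", 1:15),          # 15
               big_out = c(paste0("G", 1:40), paste0("X", 1:560)),  # 40 in
               none = paste0("X", 1:30))
  fs <- filterSets(sets, universe, min_size = 15, max_size = 500)
  expect_setequal(names(fs), c("exact", "big_out"))
  expect_length(fs$big_out, 40)
})

test_that("enrichment score matches the worked example and edge cases", {
  r <- c(g1 = 2, g2 = 1.5, g3 = 1, g4 = 0.5, g5 = 0.1)
  es <- enrichmentScore(r, c("g2", "g4"))
  expect_equal(es$es, 0.4166667, tolerance = 1e-4)
  expect_setequal(es$leading_edge, "g2")
  # single top hit -> es = 1
  expect_equal(enrichmentScore(r, "g1")$es, 1)
  # whole universe -> es = 1 with monotone climb
  all5 <- enrichmentScore(r, names(r))
  expect_equal(all5$es, 1)
  expect_true(all(diff(all5$running) > 0))
  expect_error(enrichmentScore(r, "absent"), "no overlap")
  expect_error(enrichmentScore(c(a = 0, b = 0, c = 1), "a"), "degenerate")
})

test_that("enrichment score equals the exhaustive prefix oracle on small universes", {
  set.seed(10)
  for (N in c(5, 8, 12)) {
    scores <- sort(rnorm(N), decreasing = TRUE)
    names(scores) <- paste0("g", seq_len(N))
    # every non-empty proper subset
    for (code in seq_len(2^N - 2)) {
      mask <- as.logical(bitwAnd(code, 2^(seq_len(N) - 1)))
      if (sum(abs(scores[mask])) == 0) next
      expect_equal(enrichmentScore(scores, names(scores)[mask])$es,
                   es_oracle(scores, mask), tolerance = 1e-12)
    }
  }
})

test_that("running sum returns to zero and es is bounded", {
  set.seed(11)
  scores <- sort(rnorm(200), decreasing = TRUE)
  names(scores) <- paste0("g", 1:200)
  for (i in 1:20) {
    S <- sample(names(scores), sample(2:100, 1))
    es <- enrichmentScore(scores, S)
    expect_lte(abs(es$es), 1)
    expect_lt(abs(es$running[200]), 1e-9)
  }
})

test_that("reversing the list negates the unweighted score", {
  set.seed(12)
  scores <- sort(rnorm(50), decreasing = TRUE)
  names(scores) <- paste0("g", 1:50)
  S <- sample(names(scores), 10)
  fwd <- enrichmentScore(scores, S, p = 0)$es
  rev_scores <- rev(scores)
  bwd <- enrichmentScore(rev_scores, S, p = 0)$es
  expect_equal(fwd, -bwd)
  # weighted form: holds with sign-flipped, reversed scores
  fwd1 <- enrichmentScore(scores, S, p = 1)$es
  bwd1 <- enrichmentScore(rev(-scores), S, p = 1)$es
  expect_equal(fwd1, -bwd1)
})

test_that("permutation null is seeded, calibrated at the edges, and normalizes es", {
  set.seed(13)
  scores <- sort(rnorm(300), decreasing = TRUE)
  names(scores) <- paste0("g", 1:300)
  S <- sample(names(scores), 25)
  a <- permutationNull(scores, S, n_perm = 200, seed = 99)
  b <- permutationNull(scores, S, n_perm = 200, seed = 99)
  expect_identical(a, b)
  expect_gt(a$p_perm, 0)
  expect_lte(a$p_perm, 1)
  expect_equal(sign(a$nes), sign(a$es))
  expect_error(permutationNull(scores, S, n_perm = 50), "at least 100")
})

test_that("es agrees with fgsea on a moderate example", {
  skip_if_not_installed("fgsea")
  set.seed(14)
  scores <- sort(rnorm(500), decreasing = TRUE)
  names(scores) <- paste0("g", 1:500)
  sets <- lapply(1:5, function(i) sample(names(scores), 30))
  names(sets) <- paste0("s", 1:5)
  ours <- vapply(sets, function(s) enrichmentScore(scores, s)$es, numeric(1))
  theirs <- suppressWarnings(
    fgsea::fgsea(sets, scores, nperm = 100, gseaParam = 1))
  expect_equal(ours[theirs$pathway], setNames(theirs$ES, theirs$pathway),
               tolerance = 1e-10)
})

test_that("collection-level run orders, adjusts and annotates", {
  set.seed(15)
  scores <- sort(rnorm(400), decreasing = TRUE)
  names(scores) <- paste0("g", 1:400)
  sets <- c(lapply(1:6, function(i) sample(names(scores), 25)),
            list(top = names(scores)[1:20]))
  names(sets) <- c(paste0("rand", 1:6), "TOP")
  res <- runGsea(scores, sets, min_size = 15, max_size = 500,
                 n_perm = 200, seed = 7)
  expect_equal(nrow(res), 7)
  expect_equal(res["TOP", "es"], 1)
  expect_lt(res["TOP", "p_perm"], 0.05)
  expect_equal(res$fdr, p.adjust(res$p_perm, "BH"))
  # BH on a known triple
  expect_equal(p.adjust(c(0.01, 0.02, 0.9), "BH"),
               c(0.03, 0.03, 0.9))
})
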