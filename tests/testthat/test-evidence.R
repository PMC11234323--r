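test_that("E-values follow the empirical definition", {
  aln <- random_alignment(12, 30, seed = 70)
  tr <- build_tree(aln)
  nd <- null_distribution(aln, tr, n_nulls = 5, seed = 71)
  P <- 30 * 29 / 2
  # below the null minimum: every pair per null alignment matches
  expect_equal(evalue(min(nd$pooled) - 1, nd), P)
  # at the pooled median: about P/2 (empirical count oracle)
  med <- stats::median(nd$pooled)
  expect_equal(evalue(med, nd), sum(nd$pooled >= med) / nd$M)
  expect_lt(abs(evalue(med, nd) - P / 2) / P, 0.05)
  # statistic mismatch refused
  expect_error(evalue(1, nd, stat = "mi"), "mismatch")
  # beyond the pooled maximum the tail takes over, anchored at 1/M
  eps <- 1e-9
  expect_lte(evalue(nd$pooled_max + eps, nd), 1 / nd$M)
  expect_gt(evalue(nd$pooled_max + eps, nd), 0)
  # survival monotone non-increasing
  grid <- seq(min(nd$pooled), nd$pooled_max + 5, length.out = 200)
  expect_true(all(diff(evalue(grid, nd)) <= 1e-12))
})

test_that("an alignment of identical sequences has no significant pairs", {
  aln <- rna_alignment(rep("ACGUACGUACGUACG", 6), sprintf("t%d", 1:6))
  sp <- significant_pairs(aln, seed = 3, n_nulls = 5)
  expect_false(any(sp$significant))
})

test_that("power curves are isotonic, zero at zero, and recover generators", {
  # step training data: >= 6 subs always significant, < 6 never
  subs <- rep(0:12, each = 20)
  sig <- subs >= 6
  pc <- fit_power_curve(subs, sig, mode = "single")
  expect_equal(power_value(pc, 0), 0)
  expect_equal(power_value(pc, c(5, 6, 12)), c(0, 1, 1))
  expect_true(all(diff(pc$y) >= 0))
  # logistic generator recovery within 0.1 at all training levels
  set.seed(81)
  n <- 400
  subs <- sample(0:20, n, replace = TRUE)
  pr <- plogis((subs - 8) / 2)
  sig <- runif(n) < pr
  pc <- fit_power_curve(subs, sig, mode = "single")
  lv <- sort(unique(subs[subs > 0]))
  expect_lt(max(abs(power_value(pc, lv) - plogis((lv - 8) / 2))), 0.1)
  expect_error(fit_power_curve(rep(3, 10), rep(TRUE, 10)), "degenerate")
})

test_that("expected covarying counts are sums of powers", {
  aln <- rna_alignment(rep("ACGUACGUACGUACG", 5), sprintf("t%d", 1:5))
  tr <- build_tree(aln)
  map <- count_substitutions(fitch_sample(aln, tr, seed = 1))
  curve <- fit_power_curve(rep(0:10, each = 5),
                           rep(0:10, each = 5) >= 4, mode = "single")
  pairs <- data.frame(i = c(1L, 2L), j = c(15L, 14L))
  expect_equal(expected_covarying(pairs, map, curve), 0)  # fully conserved

  aln2 <- random_alignment(10, 30, seed = 85)
  tr2 <- build_tree(aln2)
  map2 <- count_substitutions(fitch_sample(aln2, tr2, seed = 2))
  pairs2 <- data.frame(i = c(1L, 3L, 5L), j = c(30L, 28L, 26L))
  brute <- sum(sapply(1:3, function(k) {
    n <- pair_substitution_counts(map2, pairs2$i[k], pairs2$j[k])["single"]
    power_value(curve, n)
  }))
  expect_equal(expected_covarying(pairs2, map2, curve), brute)
  expect_equal(expected_covarying(pairs2[0, ], map2, curve), 0)
})

test_that("classification implements the four-way scheme", {
  expect_equal(classify(0, 4, 2)$call, "CANNOT_TELL")
  expect_equal(classify(0, 10, 9)$call, "NEGATIVE")
  expect_equal(classify(3, 1, 1)$call, "STRUCTURAL")
  expect_equal(classify(5, 20, 20)$call, "STRUCTURAL")
  expect_equal(classify(0, 12, 3)$call, "INCONSISTENT_POWER")
  expect_equal(classify(1, 6.5, 6)$call, "INCONCLUSIVE")
})

test_that("the default shipped power calibration loads and is monotone", {
  for (mode in c("single", "double")) {
    pc <- default_power_curve(mode)
    expect_equal(power_value(pc, 0), 0)
    expect_true(all(diff(pc$y) >= 0))
    expect_true(all(pc$y >= 0 & pc$y <= 1))
  }
})

test_that("E-values are calibrated at moderate thresholds (reduced world)", {
  counts05 <- counts20 <- numeric(30)
  for (r in 1:30) {
    sim <- simulate_structural_alignment(15, 60, pairs = NULL,
                                         divergence = 0.3,
                                         topology = "star", seed = 9100 + r)
    aln <- sim$alignment
    tr <- build_tree(aln)
    nd <- null_distribution(aln, tr, n_nulls = 20, seed = 9500 + r)
    sm <- score_matrix(aln, "gtest")
    ev <- evalue(sm$apc[upper.tri(sm$apc)], nd)
    counts05[r] <- sum(ev < 0.05)
    counts20[r] <- sum(ev < 0.2)
  }
  se05 <- sqrt(0.05 * 0.95 / 30)
  se20 <- sqrt(0.2 * 0.8 / 30)
  expect_lt(abs(mean(counts05) - 0.05), 3 * se05 + 1e-9)
  expect_lt(abs(mean(counts20) - 0.2), 3 * se20 + 1e-9)
})

test_that("the full analyze pipeline returns a coherent report", {
  sim <- simulate_structural_alignment(16, 50, pairs = 6, divergence = 1.2,
                                       tree = balanced_tree(16, 1.2),
                                       seed = 77)
  res <- analyze(sim$alignment, n_nulls = 10, seed = 78)
  expect_s3_class(res$pairs, "pair_evidence")
  expect_false(is.unsorted(res$pairs$evalue))
  expect_true(all(res$pairs$power_single >= 0 & res$pairs$power_single <= 1))
  expect_s3_class(res$call, "structure_call")
  tsv <- tempfile(); js <- tempfile()
  write_analysis(res, tsv, js)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), nrow(res$pairs))
  expect_true(jsonlite::validate(readLines(js, warn = FALSE)))
})
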