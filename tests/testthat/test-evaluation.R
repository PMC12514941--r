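# ROC / weighted ROC / AUC bounds / fraction sweep.

test_that("perfect and inverted rankings hit the AUC extremes", {
  rk <- labeled_ranking(1:6, 6:1, c(5, 2, 1, -1, 0, -3))
  expect_equal(roc(rk)$auc, 1)
  rev_rk <- labeled_ranking(1:6, 1:6, c(5, 2, 1, -1, 0, -3))
  expect_equal(roc(rev_rk)$auc, 0)
  expect_error(roc(labeled_ranking(1:3, 3:1, c(1, 2, 3))), "negative")
})

test_that("AUC equals the Mann-Whitney pair-counting oracle, ties included", {
  set.seed(12)
  for (i in 1:25) {
    n <- sample(10:50, 1)
    score <- sample(seq_len(8), n, replace = TRUE) + rnorm(n, 0, 0.01 * (i %% 2))
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(lab)) < 2) next
    rk <- labeled_ranking(seq_len(n), score, ifelse(lab, 1, -1))
    expect_equal(roc(rk)$auc, oracle_auc_mw(score, lab), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC library", {
  skip_if_not_installed("pROC")
  set.seed(31)
  score <- rnorm(40)
  lab <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  rk <- labeled_ranking(1:40, score, ifelse(lab, 1, -1))
  ref <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = score,
                                        quiet = TRUE, direction = "<")))
  expect_equal(roc(rk)$auc, ref, tolerance = 1e-12)
})

test_that("weighted ROC reproduces the hand-computed step construction", {
  # positives dTm {3, 1}, two negatives, order [P3, N, P1, N]
  rk <- labeled_ranking(c("p3", "n1", "p1", "n2"), c(4, 3, 2, 1),
                        c(3, -1, 1, -2))
  expect_equal(roc(rk)$auc, 0.75)
  expect_equal(weighted_roc(rk)$auc, 0.875)
  # swapping the two positives hurts the weighted AUC only
  swapped <- labeled_ranking(c("p1", "n1", "p3", "n2"), c(4, 3, 2, 1),
                             c(1, -1, 3, -2))
  expect_equal(roc(swapped)$auc, 0.75)
  expect_lt(weighted_roc(swapped)$auc, 0.875)
  # equal dTm reduces the weighted curve to the plain one exactly
  eq <- labeled_ranking(1:8, c(8, 7, 6, 5, 4, 3, 2, 1),
                        c(2, -1, 2, 2, -1, -1, 2, -1))
  expect_equal(weighted_roc(eq)$auc, roc(eq)$auc)
  broken <- labeled_ranking(1:3, 3:1, c(2, 1, -1))
  broken$dtm[1] <- NA   # a positive that lost its measurement
  expect_error(weighted_roc(broken), "dtm")
})

test_that("ROC curves start at (0,0), end at (1,1), and never decrease", {
  set.seed(9)
  for (i in 1:10) {
    n <- 30
    rk <- labeled_ranking(1:n, sample(1:5, n, TRUE),
                          ifelse(runif(n) < 0.4, runif(n, 0.5, 4), -1))
    for (res in list(roc(rk), weighted_roc(rk))) {
      pts <- res$points
      expect_equal(pts[1, ], c(fpr = 0, tpr = 0))
      expect_equal(unname(pts[nrow(pts), ]), c(1, 1), tolerance = 1e-12)
      expect_true(all(diff(pts[, 1]) >= -1e-12))
      expect_true(all(diff(pts[, 2]) >= -1e-12))
    }
  }
})

test_that("AUC bounds bracket every scenario and collapse when U = 0", {
  rk <- labeled_ranking(1:8, 8:1, c(3, NA, 1, NA, -1, NA, 0.5, -2))
  b <- auc_bounds(rk)
  expect_true(all(b$per_k$upper >= b$per_k$lower - 1e-12))
  expect_equal(b$per_k$k, 0:3)
  plain <- b$per_k$lower[1]
  expect_gte(b$upper, plain)
  expect_lte(b$lower, plain)
  # flipping a bottom-ranked untested positive lowers the AUC
  worst <- labeled_ranking(1:5, 5:1, c(2, 1, -1, -2, NA))
  bw <- auc_bounds(worst)
  expect_lt(bw$per_k$lower[2], bw$per_k$lower[1])
  # no untested: bounds equal the plain AUC for every k
  none <- labeled_ranking(1:4, 4:1, c(2, -1, 1, -2))
  bn <- auc_bounds(none)
  expect_equal(bn$lower, bn$upper)
  expect_equal(bn$lower, roc(none)$auc)
})

test_that("the fraction sweep is seeded, exact at the endpoints, and bounded", {
  rk <- labeled_ranking(1:10, 10:1,
                        c(3, NA, 1, NA, -1, NA, 0.5, NA, -2, NA))
  fs1 <- fraction_sweep(rk, c(0, 0.4, 1), reps = 200, seed = 7)
  fs2 <- fraction_sweep(rk, c(0, 0.4, 1), reps = 200, seed = 7)
  expect_identical(fs1, fs2)
  b <- auc_bounds(rk)
  expect_equal(fs1$mean_auc[1], b$per_k$lower[1])
  # f = 1 is deterministic: all untested flipped
  expect_equal(fs1$mean_auc[3], b$per_k$upper[nrow(b$per_k)])
  k <- round(0.4 * 5)
  expect_gte(fs1$mean_auc[2], b$per_k$lower[b$per_k$k == k] - 1e-12)
  expect_lte(fs1$mean_auc[2], b$per_k$upper[b$per_k$k == k] + 1e-12)
  expect_error(fraction_sweep(labeled_ranking(1, 1, 1), 0.5), "untested")
  # a single untested entry must flip that entry, not a random row
  one <- labeled_ranking(1:4, 4:1, c(3, NA, 1, -2))
  expect_equal(fraction_sweep(one, 1, reps = 20, seed = 1)$mean_auc,
               auc_bounds(one)$per_k$upper[2])
})
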