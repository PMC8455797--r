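test_that("confusion counts are exact pixel tallies", {
  t0 <- matrix(0L, 10, 10)
  t0[1:5, 1:6] <- 1L
  cc <- confusionCounts(t0, t0)
  expect_equal(cc, list(tp = 30L, tn = 70L, fp = 0L, fn = 0L))
  allFg <- matrix(1L, 10, 10)
  cc2 <- confusionCounts(allFg, matrix(0L, 10, 10))
  expect_equal(cc2$fp, 100L)
  expect_equal(cc2$tp + cc2$tn + cc2$fn, 0L)
  # hand count on a 4x4 grid: 3-px truth, 2 overlap + 1 extra prediction
  tr <- matrix(0L, 4, 4); tr[1, 1:3] <- 1L
  pr <- matrix(0L, 4, 4); pr[1, 2:3] <- 1L; pr[3, 3] <- 1L
  expect_equal(confusionCounts(pr, tr),
               list(tp = 2L, tn = 12L, fp = 1L, fn = 1L))
  expect_error(confusionCounts(matrix(0, 2, 2), matrix(0, 3, 3)),
               "identical shapes")
})

test_that("segmentation metrics match their defining formulas", {
  perfect <- segMetrics(list(tp = 30, tn = 70, fp = 0, fn = 0))
  expect_equal(unname(perfect), rep(1, 4))
  m <- segMetrics(list(tp = 2, tn = 11, fp = 1, fn = 1))
  expect_equal(unname(m["dsc"]), 4 / 6, tolerance = 1e-12)
  expect_equal(unname(m["sensitivity"]), 2 / 3)
  expect_equal(unname(m["specificity"]), 11 / 12)
  expect_equal(unname(m["accuracy"]), 13 / 15)
  # empty-denominator policy: sentinel, not silent 0 or 1
  deg <- segMetrics(list(tp = 0, tn = 9, fp = 0, fn = 0))
  expect_true(is.na(deg["sensitivity"]))
  expect_true(is.na(deg["dsc"]))
  expect_equal(unname(deg["specificity"]), 1)
  expect_error(segMetrics(list(tp = 0, tn = 0, fp = 0, fn = 0)),
               "all-zero")
})

test_that("per-image summaries report mean and n-1 sd", {
  t1 <- matrix(0L, 6, 6); t1[2:4, 2:4] <- 1L
  p1 <- t1
  p2 <- t1; p2[2, 2] <- 0L
  ms <- segMetricsSet(list(p1, p2), list(t1, t1))
  expect_equal(nrow(ms$perImage), 2)
  d2 <- 2 * 8 / (2 * 8 + 0 + 1)
  expect_equal(unname(ms$mean["dsc"]), mean(c(1, d2)))
  expect_equal(unname(ms$sd["dsc"]), sd(c(1, d2)))
})

test_that("ROC endpoints behave for perfect, inverted and flat rankings", {
  truth <- matrix(c(rep(1L, 20), rep(0L, 30)), 5)
  perfect <- rocPrCurves(truth + 0, truth)
  expect_equal(perfect$roc$auc, 1)
  expect_equal(perfect$pr$auc, 1)
  inverted <- rocPrCurves(1 - truth, truth)
  expect_equal(inverted$roc$auc, 0)
  flat <- rocPrCurves(matrix(0.5, 5, 10), truth)
  expect_equal(flat$roc$auc, 0.5)
  expect_error(rocPrCurves(matrix(0.5, 2, 2), matrix(1L, 2, 2)),
               "single class")
})

test_that("trapezoidal ROC AUC equals the Mann-Whitney oracle", {
  withr::with_seed(4, {
    for (i in 1:20) {
      n <- sample(20:200, 1)
      y <- rbinom(n, 1, 0.4)
      if (sum(y) == 0 || sum(y) == n) next
      p <- round(runif(n), sample(1:3, 1))   # coarse grid forces ties
      auc <- rocPrCurves(p, y)$roc$auc
      pos <- p[y == 1]; neg <- p[y == 0]
      cmp <- outer(pos, neg, function(a, b)
        (a > b) + 0.5 * (a == b))
      expect_equal(auc, mean(cmp), tolerance = 1e-9)
    }
  })
})

test_that("ROC AUC agrees with an established implementation", {
  withr::with_seed(5, {
    y <- rbinom(300, 1, 0.3)
    p <- plogis(rnorm(300) + 1.2 * y)
    ours <- rocPrCurves(p, y)$roc$auc
    ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE)))
    expect_equal(ours, ref, tolerance = 1e-9)
  })
})

test_that("agreement statistics reproduce the hand-worked fixture", {
  # pairs (10,12), (20,18), (30,30): diffs -2, 2, 0
  ag <- agreementStats(c(10, 20, 30), c(12, 18, 30))
  expect_equal(ag$bias, 0)
  expect_equal(ag$sdDiff, 2)
  expect_equal(ag$loaLow, -3.92)
  expect_equal(ag$loaHigh, 3.92)
  expect_equal(ag$n, 3L)

  a <- c(3, 9, 27, 12)
  same <- agreementStats(a, a)
  expect_equal(same$r, 1)
  expect_equal(same$bias, 0)
  expect_equal(same$loaLow, 0)
  expect_equal(same$loaHigh, 0)
  expect_equal(same$fractionWithin, 1)

  offset <- agreementStats(a + 5, a)
  expect_equal(offset$r, 1)
  expect_equal(offset$bias, 5)
  expect_equal(offset$loaLow, 5)

  expect_warning(agreementStats(rep(2, 4), c(1, 2, 3, 4)), "variance")
  expect_error(agreementStats(1:2, 1:2), "3 pairs")
})
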