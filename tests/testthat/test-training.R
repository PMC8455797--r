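test_that("dice loss matches hand-counted confusion cells", {
  truth <- c(1, 1, 1, 0, 0, 0)
  expect_equal(diceLoss(truth, truth, smooth = 0), 0)
  expect_equal(diceLoss(c(0, 0, 0, 1, 1, 0), truth, smooth = 0), 1)
  # tp = 2, fp = 1, fn = 1 -> 1 - 4/6
  expect_equal(diceLoss(c(1, 1, 0, 1, 0, 0), truth, smooth = 0), 1 - 4 / 6)
  expect_error(diceLoss(c(0.5, 0.5), c(1, 0, 1)), "identical shapes")
  expect_error(diceLoss(c(0, 0), c(0, 0), smooth = 0), "empty")
})

test_that("dice loss stays in [0, 1] and links to the DSC", {
  withr::with_seed(1, {
    for (i in 1:50) {
      p <- runif(40)
      t0 <- rbinom(40, 1, 0.4)
      l <- diceLoss(p, t0, smooth = runif(1, 0, 2))
      expect_gte(l, 0)
      expect_lte(l, 1)
      pb <- as.integer(p >= 0.5)
      if (sum(pb) + sum(t0) > 0) {
        cc <- confusionCounts(matrix(pb, 5), matrix(t0, 5))
        expect_equal(1 - diceLoss(pb, t0, smooth = 0),
                     unname(segMetrics(cc)["dsc"]))
      }
    }
  })
})

test_that("dice gradient agrees with finite differences", {
  withr::with_seed(2, {
    p <- runif(20, 0.05, 0.95)
    t0 <- rbinom(20, 1, 0.5)
    g <- SpineVCR:::diceLossGrad(p, t0, smooth = 1)
    eps <- 1e-6
    for (j in c(1, 7, 20)) {
      pp <- p; pp[j] <- p[j] + eps
      pm <- p; pm[j] <- p[j] - eps
      num <- (diceLoss(pp, t0, 1) - diceLoss(pm, t0, 1)) / (2 * eps)
      expect_equal(g[j], num, tolerance = 1e-5)
    }
  })
})

test_that("plateau schedule reduces after patience epochs without gain", {
  # constant monitored loss, patience 2, factor 0.1: reduction at epoch 3
  expect_equal(plateauTrace(c(1, 1, 1), lr0 = 1e-3, factor = 0.1,
                            patience = 2),
               c(1e-3, 1e-3, 1e-4))
  # improvement resets the wait counter
  expect_equal(plateauTrace(c(1, 1, 0.5, 0.5, 0.5), 1e-3, 0.1, 2),
               c(1e-3, 1e-3, 1e-3, 1e-3, 1e-4))
  # floor at minLr; trace is non-increasing
  tr <- plateauTrace(rep(1, 20), 1e-3, 0.1, 2, minLr = 1e-5)
  expect_true(all(diff(tr) <= 0))
  expect_equal(min(tr), 1e-5)
})

microSet <- function(n, seed) {
  ds <- generatePhantomDataset(
    phantomSpec(imageHeight = 64, imageWidth = 64, noiseSd = 6), n,
    seed = seed)
  list(img = lapply(ds, function(s) phantomImage(s) / 255),
       msk = lapply(ds, phantomMask))
}

test_that("one epoch on one sample leaves the learning rate untouched", {
  d <- microSet(2, seed = 3)
  m <- buildModel(modelConfig(depth = 2L, baseFilters = 2L,
                              inputSize = c(64L, 64L)), seed = 1L)
  fit <- trainModel(m, d$img[1], d$msk[1], d$img[2], d$msk[2],
                    trainConfig(epochs = 1, batchSize = 1, seed = 1L))
  expect_equal(nrow(fit$history), 1)
  expect_equal(fit$history$lr, 0.001)
})

test_that("a short run reduces the validation loss and reproduces exactly", {
  d <- microSet(8, seed = 4)
  cfg <- trainConfig(epochs = 4, batchSize = 3, seed = 9L)
  mcfg <- modelConfig(depth = 3L, baseFilters = 4L, inputSize = c(64L, 64L))
  fit1 <- trainModel(buildModel(mcfg, 7L), d$img[1:6], d$msk[1:6],
                     d$img[7:8], d$msk[7:8], cfg)
  expect_lt(fit1$history$valLoss[4], fit1$history$valLoss[1])
  fit2 <- trainModel(buildModel(mcfg, 7L), d$img[1:6], d$msk[1:6],
                     d$img[7:8], d$msk[7:8], cfg)
  expect_identical(fit1$history, fit2$history)
})

test_that("cross-validation partitions every sample exactly once", {
  d <- microSet(10, seed = 5)
  cfg <- trainConfig(epochs = 1, batchSize = 4, seed = 21L, folds = 5L)
  mcfg <- modelConfig(depth = 2L, baseFilters = 2L, inputSize = c(64L, 64L))
  cv <- crossValidate(d$img, d$msk, cfg, mcfg)
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_equal(as.vector(table(cv$folds)), rep(2L, 5))
  expect_equal(nrow(cv$perFold), 5)
  expect_true(all(c("dsc", "sensitivity") %in% cv$summary$metric))
  # deterministic assignment
  cv2assign <- withr::with_seed(99, {
    SpineVCR:::withSeed(cfg$seed, sample(rep_len(1:5, 10)))
  })
  expect_identical(cv$folds, cv2assign)
  expect_error(crossValidate(d$img[1:3], d$msk[1:3], cfg, mcfg), "folds")
})
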