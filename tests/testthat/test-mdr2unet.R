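tinyCfg <- function(...) {
  args <- modifyList(list(depth = 3L, baseFilters = 4L,
                          dilationRates = c(2L, 4L, 8L, 16L),
                          inputSize = c(32L, 32L)), list(...))
  do.call(modelConfig, args)
}

test_that("dilated kernels span the expected receptive extent", {
  expect_equal(effectiveKernel(3, 1), 3L)
  expect_equal(effectiveKernel(3, 2), 5L)
  expect_equal(effectiveKernel(3, 16), 33L)
  expect_equal(effectiveKernel(5, 3), 13L)
  expect_error(effectiveKernel(4, 2), "odd")
})

test_that("invalid model configurations are rejected", {
  expect_error(modelConfig(depth = 1), "depth")
  expect_error(modelConfig(dilationRates = c(4, 2)), "increasing")
  expect_error(modelConfig(depth = 5, inputSize = c(100, 100)),
               "divisible")
  expect_error(modelConfig(recurrenceSteps = 0), "recurrenceSteps")
})

test_that("forward pass preserves spatial size with sigmoid output", {
  m <- buildModel(tinyCfg(), seed = 2L)
  img <- matrix(runif(32 * 32), 32, 32)
  out <- predictMask(m, img)
  expect_equal(dim(out$prob), c(32L, 32L))
  expect_true(all(out$prob >= 0 & out$prob <= 1))
  expect_true(all(is.finite(out$prob)))
  # scaled configuration
  m2 <- buildModel(tinyCfg(depth = 4L, baseFilters = 8L,
                           inputSize = c(64L, 64L)), seed = 2L)
  out2 <- predictMask(m2, matrix(runif(64 * 64), 64, 64))
  expect_equal(dim(out2$prob), c(64L, 64L))
})

test_that("zero input propagates to zero through MDRB (zero biases)", {
  m <- buildModel(tinyCfg(), seed = 3L)
  x <- array(0, c(32, 32, 1, 1))
  y <- SpineVCR:::blockFw(m@net$enc[[1]], x, training = TRUE)$y
  expect_equal(max(abs(y)), 0)
})

test_that("MDRB concatenates one branch per rate and restores the width", {
  m <- buildModel(tinyCfg(baseFilters = 16L), seed = 1L)
  mdrb <- m@net$enc[[1]]
  expect_equal(mdrb$kind, "MDRB")
  expect_length(mdrb$branchConv, 4)
  # bottleneck reduces the quadrupled concat width back to the block width
  expect_equal(dim(mdrb$bottleneck$params$W), c(1L, 1L, 64L, 16L))
  expect_equal(vapply(mdrb$branchConv, function(l) l$dilation, integer(1)),
               c(2L, 4L, 8L, 16L))
  # single-rate configuration still builds
  m1 <- buildModel(tinyCfg(dilationRates = 2L), seed = 1L)
  expect_equal(dim(m1@net$enc[[1]]$bottleneck$params$W), c(1L, 1L, 4L, 4L))
  out <- predictMask(m1, matrix(runif(32 * 32), 32, 32))
  expect_equal(dim(out$prob), c(32L, 32L))
})

test_that("recurrent blocks share weights across steps", {
  n1 <- modelParameterCount(buildModel(tinyCfg(recurrenceSteps = 1L), 1L))
  n3 <- modelParameterCount(buildModel(tinyCfg(recurrenceSteps = 3L), 1L))
  expect_equal(n1, n3)
  # a single-step block degenerates to a plain residual conv block
  m <- buildModel(tinyCfg(recurrenceSteps = 1L), seed = 4L)
  expect_equal(m@net$enc[[2]]$steps, 1L)
  out <- predictMask(m, matrix(runif(32 * 32), 32, 32))
  expect_true(all(is.finite(out$prob)))
})

test_that("predictions threshold monotonically and reject wrong sizes", {
  m <- buildModel(tinyCfg(), seed = 5L)
  img <- matrix(runif(32 * 32), 32, 32)
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th)
    sum(predictMask(m, img, th)$mask), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(predictMask(m, matrix(0.5, 16, 16)),
               "preprocessRadiograph")
  expect_error(predictMask(m, img, threshold = 0), "threshold")
})

test_that("weights serialise and restore to identical predictions", {
  m <- buildModel(tinyCfg(), seed = 6L)
  img <- matrix(runif(32 * 32), 32, 32)
  p0 <- predictMask(m, img)$prob
  f <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, f)
  m2 <- loadModel(f)
  expect_equal(predictMask(m2, img)$prob, p0)
  expect_equal(modelConfigOf(m2), modelConfigOf(m))
  # config side-car is valid JSON mirroring the config
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$depth, 3L)
})

test_that("identical seeds give identical initial weights", {
  a <- modelWeights(buildModel(tinyCfg(), seed = 11L))
  b <- modelWeights(buildModel(tinyCfg(), seed = 11L))
  d <- modelWeights(buildModel(tinyCfg(), seed = 12L))
  expect_identical(a, b)
  expect_false(identical(a, d))
})
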