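test_that("compression fraction sets the true VCR by construction", {
  s <- generatePhantom(compressedSpec(0.4, 3L))
  expect_equal(trueVCR(s), 40)
  expect_equal(compressedIndex(s), 3L)

  s0 <- generatePhantom(smallSpec())
  expect_equal(trueVCR(s0), 0)
  heights <- apply(cornerTruth(s0), 3, function(co)
    sqrt(sum((co["AS", ] - co["AI", ])^2)))
  expect_equal(max(heights) - min(heights), 0)
})

test_that("generation is deterministic for a fixed seed", {
  a <- generatePhantom(compressedSpec(0.3, 3L, seed = 9L))
  b <- generatePhantom(compressedSpec(0.3, 3L, seed = 9L))
  expect_identical(phantomImage(a), phantomImage(b))
  expect_identical(phantomMask(a), phantomMask(b))
  c2 <- generatePhantom(compressedSpec(0.3, 3L, seed = 10L))
  expect_false(identical(phantomImage(a), phantomImage(c2)))
})

test_that("masks have exactly nVertebrae well-separated components", {
  for (sp in list(smallSpec(), compressedSpec(0.5, 2L),
                  smallSpec(tiltDegrees = 8), smallSpec(nVertebrae = 7),
                  smallSpec(anteriorSide = "right"))) {
    s <- generatePhantom(sp)
    lab <- labelComponents(phantomMask(s))
    expect_equal(max(lab), sp$nVertebrae)
    # pairwise non-adjacency: a 1-px 8-neighbourhood dilation must not
    # merge components (>= 1 background pixel between any two bodies)
    m <- phantomMask(s)
    H <- nrow(m); W <- ncol(m)
    p <- matrix(0L, H + 2, W + 2)
    p[2:(H + 1), 2:(W + 1)] <- m
    dil <- p[1:H, 1:W] + p[1:H, 2:(W + 1)] + p[1:H, 3:(W + 2)] +
      p[2:(H + 1), 1:W] + p[2:(H + 1), 2:(W + 1)] + p[2:(H + 1), 3:(W + 2)] +
      p[3:(H + 2), 1:W] + p[3:(H + 2), 2:(W + 1)] + p[3:(H + 2), 3:(W + 2)]
    expect_equal(max(labelComponents(matrix(as.integer(dil > 0), H, W))),
                 sp$nVertebrae)
  }
})

test_that("anterior wedging preserves posterior height and trims anterior", {
  sp <- compressedSpec(0.4, 3L)
  s <- generatePhantom(sp)
  co <- cornerTruth(s)
  aH <- sqrt(sum((co["AS", , 3] - co["AI", , 3])^2))
  pH <- sqrt(sum((co["PS", , 3] - co["PI", , 3])^2))
  expect_equal(aH, (1 - 0.4) * sp$bodyHeight)
  expect_equal(pH, sp$bodyHeight)
})

test_that("VCR formula applied to corner truth recovers the target exactly", {
  for (f in c(0, 0.1, 0.25, 0.4)) {
    sp <- if (f > 0) compressedSpec(f, 3L) else smallSpec()
    s <- generatePhantom(sp)
    co <- cornerTruth(s)
    h <- apply(co, 3, function(q) sqrt(sum((q["AS", ] - q["AI", ])^2)))
    expect_equal(computeVCR(h[2], h[3], h[4]), 100 * f, tolerance = 1e-12)
  }
})

test_that("noise-free image thresholded at the level midpoint is the mask", {
  sp <- smallSpec(noiseSd = 0, tiltDegrees = 5)
  s <- generatePhantom(sp)
  mid <- (sp$backgroundLevel + sp$bodyLevel) / 2
  expect_identical(matrix(as.integer(phantomImage(s) > mid), 128, 128),
                   phantomMask(s))
})

test_that("invalid specs are rejected with the violated invariant named", {
  expect_error(phantomSpec(nVertebrae = 2), "nVertebrae")
  expect_error(smallSpec(compressedIndex = 1L, compressionFraction = 0.2),
               "interior")
  expect_error(smallSpec(compressedIndex = 5L, compressionFraction = 0.2),
               "interior")
  expect_error(smallSpec(compressedIndex = 3L, compressionFraction = 1),
               "compressionFraction")
  expect_error(smallSpec(bodyHeight = 40),  "column height")
  expect_error(smallSpec(compressionFraction = 0.2), "compressedIndex")
  expect_error(generatePhantom(smallSpec(bodyWidth = 110,
                                         tiltDegrees = 45)), "bounds")
})

test_that("datasets respect count, compression range and determinism", {
  tmpl <- smallSpec()
  ds <- generatePhantomDataset(tmpl, 12, seed = 7,
                               compressionRange = c(0.2, 0.5))
  expect_length(ds, 12)
  vcrs <- vapply(ds, trueVCR, numeric(1))
  expect_true(all(vcrs >= 20 & vcrs <= 50))
  for (s in ds)
    expect_equal(max(labelComponents(phantomMask(s))), tmpl$nVertebrae)
  ds2 <- generatePhantomDataset(tmpl, 12, seed = 7,
                                compressionRange = c(0.2, 0.5))
  expect_identical(lapply(ds, phantomImage), lapply(ds2, phantomImage))
  expect_error(generatePhantomDataset(tmpl, 0), "nSamples")
})

test_that("written datasets round-trip through PNG and manifest", {
  dir <- withr::local_tempdir()
  ds <- generatePhantomDataset(smallSpec(), 3, seed = 5)
  manifest <- writePhantomDataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_length(list.files(dir, pattern = "_img\\.png$"), 3)
  expect_length(list.files(dir, pattern = "_mask\\.png$"), 3)
  back <- png::readPNG(file.path(dir, manifest$mask[2]))
  expect_identical(matrix(as.integer(back > 0.5), 128, 128),
                   phantomMask(ds[[2]]))
  rt <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(rt$trueVcrPercent, vapply(ds, trueVCR, numeric(1)))
})
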