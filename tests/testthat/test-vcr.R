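test_that("instances are separated and ordered craniocaudally", {
  s <- generatePhantom(smallSpec())
  sep <- separateInstances(phantomMask(s))
  expect_length(sep$instances, 5)
  rows <- vapply(sep$instances, function(i) i$centroid[1], numeric(1))
  expect_true(all(diff(rows) > 0))
  # two components are not enough for any compression ratio
  m2 <- matrix(0L, 32, 32)
  m2[2:8, 5:20] <- 1L
  m2[14:20, 5:20] <- 1L
  expect_error(separateInstances(m2), "at least 3")
})

test_that("ordering is tolerant to a tilted column", {
  s0 <- generatePhantom(compressedSpec(0.35, 2L, noiseSd = 0))
  st <- generatePhantom(compressedSpec(0.35, 2L, noiseSd = 0,
                                       tiltDegrees = 10))
  for (s in list(s0, st)) {
    rep <- measureVCR(phantomMask(s))
    expect_equal(flaggedLevel(rep), 2L)
    areas <- vertebraTable(rep)$area
    # compressed body is the smallest, and sits second in the order
    expect_equal(which.min(areas), 2L)
  }
})

test_that("corners of an axis-aligned rectangle are its vertices", {
  m <- matrix(0L, 100, 100)
  m[11:70, 21:60] <- 1L    # 60 tall (anterior height), 40 wide
  inst <- list(label = 1L,
               pixels = as.matrix(expand.grid(row = 10:69, col = 20:59)),
               centroid = c(39.5, 39.5), area = 2400L)
  fc <- findCorners(inst, "left", c(1, 0))
  expect_equal(unname(fc$corners["AS", ]), c(10, 20))
  expect_equal(unname(fc$corners["AI", ]), c(69, 20))
  expect_equal(unname(fc$corners["PS", ]), c(10, 59))
  expect_equal(unname(fc$corners["PI", ]), c(69, 59))
  expect_equal(fc$anteriorHeight, 60)
  # anterior on the right flips the anterior/posterior corner pairs
  fcR <- findCorners(inst, "right", c(1, 0))
  expect_equal(unname(fcR$corners["AS", ]), c(10, 59))
  # degenerate line-like component is rejected
  line <- list(label = 1L, pixels = cbind(row = 0:30, col = rep(4L, 31)),
               centroid = c(15, 4), area = 31L)
  expect_error(findCorners(line, "left", c(1, 0)), "degenerate")
})

test_that("measured trapezoid heights track the generator's corner truth", {
  sp <- compressedSpec(0.5, 3L, noiseSd = 0)
  s <- generatePhantom(sp)
  rep <- measureVCR(phantomMask(s))
  truthH <- apply(cornerTruth(s), 3, function(q)
    sqrt(sum((q["AS", ] - q["AI", ])^2)))
  expect_lt(max(abs(vertebraTable(rep)$anteriorHeight - truthH)), 1.01)
})

test_that("anterior height is rotation-tolerant within a pixel", {
  h0 <- vertebraTable(measureVCR(phantomMask(
    generatePhantom(compressedSpec(0.4, 3L, noiseSd = 0)))))$anteriorHeight
  h15 <- vertebraTable(measureVCR(phantomMask(
    generatePhantom(compressedSpec(0.4, 3L, noiseSd = 0,
                                   tiltDegrees = 15)))))$anteriorHeight
  expect_lt(max(abs(h0 - h15)), 1.5)
})

test_that("the VCR formula matches an independent arithmetic oracle", {
  expect_equal(computeVCR(10, 10, 10), 0)
  expect_equal(computeVCR(30, 15, 30), 50)
  expect_equal(computeVCR(28, 21, 32), 30)
  withr::with_seed(11, {
    v1 <- runif(1000, 1, 60)
    v2 <- runif(1000, 0, 60)
    v3 <- runif(1000, 1, 60)
    oracle <- 100 - 200 * v2 / (v1 + v3)
    got <- mapply(computeVCR, v1, v2, v3)
    expect_lt(max(abs(got - oracle)), 1e-9)
    # scale invariance
    k <- runif(1, 0.1, 9)
    expect_equal(mapply(computeVCR, k * v1, k * v2, k * v3), got,
                 tolerance = 1e-12)
  })
  expect_error(computeVCR(0, 5, 0), "zero")
  # taller-than-neighbours levels go negative, unclamped
  expect_lt(computeVCR(10, 12, 10), 0)
})

test_that("severity grading uses left-closed intervals", {
  expect_equal(as.character(gradeVCR(0)), "none")
  expect_equal(as.character(gradeVCR(50)), "severe")
  expect_equal(as.character(gradeVCR(c(19.99, 20, 24.99, 25, 39.99, 40))),
               c("none", "mild", "mild", "moderate", "moderate", "severe"))
  expect_equal(as.character(gradeVCR(30, cuts = c(5, 10, 60))), "moderate")
})

test_that("full measurement recovers the generator's compression", {
  s <- generatePhantom(compressedSpec(0.4, 3L, noiseSd = 0))
  rep <- measureVCR(phantomMask(s))
  res <- vcrResults(rep)
  expect_equal(nrow(res), 3)           # 5 vertebrae -> 3 interior levels
  expect_lt(abs(res$vcrPercent[res$levelIndex == 3] - 40), 5)
  expect_equal(flaggedLevel(rep), 3L)
  expect_equal(as.character(res$grade[res$levelIndex == 3]), "severe")
  # uncompressed phantom: all levels near zero
  s0 <- generatePhantom(smallSpec(noiseSd = 0))
  expect_true(all(abs(vcrResults(measureVCR(phantomMask(s0)))$vcrPercent)
                  < 5))
  # determinism
  expect_identical(vcrResults(measureVCR(phantomMask(s))), res)
})

test_that("heights propagate to original pixels and millimetres", {
  s <- generatePhantom(compressedSpec(0.4, 3L, noiseSd = 0))
  tf <- GeomTransform(0.5, c(10, 10), c(256, 256))
  rep <- measureVCR(phantomMask(s), transform = tf,
                    spacingMm = c(0.2, 0.2))
  tab <- vertebraTable(rep)
  expect_equal(tab$anteriorHeightOrig, tab$anteriorHeight / 0.5)
  expect_equal(tab$anteriorHeightMm, tab$anteriorHeight / 0.5 * 0.2)
  # report writer emits parseable JSON + CSV
  stem <- file.path(withr::local_tempdir(), "report")
  writeVCRReport(rep, stem)
  back <- read.csv(paste0(stem, ".csv"))
  expect_equal(back$vcrPercent, vcrResults(rep)$vcrPercent)
  js <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(js$flagged, 3L)
})
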