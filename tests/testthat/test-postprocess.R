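blobMask <- function(H = 32, W = 32, rects = list()) {
  m <- matrix(0L, H, W)
  for (r in rects) m[r[1]:r[2], r[3]:r[4]] <- 1L
  m
}

test_that("under-sized components are removed, others untouched", {
  # areas 400, 380, 3
  m <- blobMask(64, 64, list(c(2, 21, 2, 21), c(30, 48, 30, 49)))
  m[60, 60:62] <- 1L
  out <- removeSmall(m, postprocConfig(10, "absolute"))
  expect_equal(max(labelComponents(out)), 2)
  expect_equal(sum(out), 400 + 380)
  # all components above threshold: identity
  expect_identical(removeSmall(m, postprocConfig(2, "absolute")), m)
  # empty mask passes through
  expect_identical(removeSmall(matrix(0L, 8, 8)), matrix(0L, 8, 8))
})

test_that("fractional threshold uses the median component area", {
  # areas 100, 100, 20: median 100, threshold 25 removes the 20-px blob
  m <- blobMask(40, 40, list(c(1, 10, 1, 10), c(15, 24, 1, 10),
                             c(30, 33, 1, 5)))
  out <- removeSmall(m, postprocConfig(0.25, "fraction"))
  expect_equal(sum(out), 200)
  expect_equal(max(labelComponents(out)), 2)
})

test_that("strict 8-neighbour fill closes single voids only", {
  m <- blobMask(9, 9, list(c(2, 6, 2, 6)))
  m[4, 4] <- 0L
  filled <- fillHoles(m, postprocConfig())
  expect_equal(filled[4, 4], 1L)
  expect_equal(sum(filled), 25)
  # a background pixel with any background neighbour stays background
  edge <- blobMask(9, 9, list(c(2, 6, 2, 6)))
  edge[2, 2] <- 0L   # corner void touches outside background diagonally
  expect_identical(fillHoles(edge, postprocConfig()), edge)
  # 2x2 holes are invariant under the strict rule but closed by flood mode
  m2 <- blobMask(10, 10, list(c(2, 8, 2, 8)))
  m2[4:5, 4:5] <- 0L
  expect_identical(fillHoles(m2, postprocConfig()), m2)
  flood <- fillHoles(m2, postprocConfig(fillMode = "flood"))
  expect_equal(sum(flood), 49)
})

test_that("iterative fill converges where a single pass cannot", {
  # an L-shaped cavity: one pixel becomes fillable only after its
  # neighbour is filled
  m <- blobMask(9, 9, list(c(2, 8, 2, 8)))
  m[5, 4] <- 0L
  m[5, 5] <- 0L
  one <- fillHoles(m, postprocConfig(maxFillIterations = 1))
  conv <- fillHoles(m, postprocConfig())
  expect_identical(one, m)        # 2-wide cavity: nothing strict-fillable
  expect_identical(conv, m)
  m3 <- blobMask(9, 9, list(c(2, 8, 2, 8)))
  m3[5, 5] <- 0L
  expect_equal(sum(fillHoles(m3, postprocConfig(maxFillIterations = 1))),
               49)
})

test_that("clean removes specks then fills, and is idempotent", {
  s <- generatePhantom(compressedSpec(0.3, 3L, noiseSd = 0))
  truth <- phantomMask(s)
  corrupted <- truth
  # specks in the anterior margin, always clear of the column (bodies span
  # columns ~42-86 in this spec)
  withr::with_seed(8, {
    for (i in 1:5) {
      r <- sample(2:124, 1)
      c2 <- sample(3:35, 1)
      corrupted[r:(r + sample(0:2, 1)), c2] <- 1L  # 1-3 px specks
    }
  })
  # punch single-pixel voids whose full 8-neighbourhood is foreground
  inner <- matrix(0L, 128, 128)
  inner[2:127, 2:127] <-
    truth[1:126, 1:126] * truth[1:126, 2:127] * truth[1:126, 3:128] *
    truth[2:127, 1:126] * truth[2:127, 3:128] *
    truth[3:128, 1:126] * truth[3:128, 2:127] * truth[3:128, 3:128]
  corrupted[which(inner == 1L)[c(10, 400)]] <- 0L
  cleaned <- cleanMask(corrupted)
  expect_identical(cleaned, truth)
  expect_identical(cleanMask(cleaned), cleaned)
  expect_identical(cleanMask(matrix(0L, 16, 16)), matrix(0L, 16, 16))
})

test_that("removal never adds and filling never removes foreground", {
  withr::with_seed(3, {
    for (i in 1:10) {
      m <- matrix(rbinom(400, 1, 0.35), 20, 20)
      rs <- removeSmall(m, postprocConfig())
      fh <- fillHoles(m, postprocConfig())
      expect_true(all(rs <= m))
      expect_true(all(fh >= m))
      cl <- cleanMask(m)
      expect_lte(max(labelComponents(cl)), max(labelComponents(m)))
    }
  })
})
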