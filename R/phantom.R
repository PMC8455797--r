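#' Specification of a synthetic lateral-spine phantom
#'
#' Describes a craniocaudal stack of bright trapezoidal vertebral bodies
#' separated by dark disc gaps on a noisy soft-tissue background, with one
#' vertebra optionally wedged anteriorly by a known fraction of its height.
#' Anterior is the left image edge by default (\code{anteriorSide} mirrors
#' it). Geometry defaults scale with the image size so the same template
#' works at 128 or 512 pixels.
#'
#' @param imageHeight,imageWidth image size in pixels.
#' @param nVertebrae number of vertebral bodies (>= 3; the compression ratio
#'   needs two neighbours).
#' @param bodyWidth,bodyHeight vertebral body size in pixels; defaults derived
#'   from the image size.
#' @param gap inter-vertebral disc space in pixels.
#' @param compressedIndex 1-based craniocaudal index of the compressed
#'   vertebra, or \code{NA} for none; must be interior (neither first nor
#'   last).
#' @param compressionFraction fractional loss of anterior height, in [0, 1).
#' @param tiltDegrees global rotation of the column about the image centre.
#' @param noiseSd additive Gaussian noise standard deviation (8-bit units).
#' @param backgroundLevel,bodyLevel 8-bit intensities of soft tissue and bone.
#' @param anteriorSide \code{"left"} or \code{"right"}.
#' @param seed integer RNG seed; generation is deterministic given the spec.
#' @return A validated list of class \code{"PhantomSpec"}.
#' @examples
#' sp <- phantomSpec(imageHeight = 128, imageWidth = 128,
#'                   compressedIndex = 3, compressionFraction = 0.3)
#' sp$bodyHeight
#' @export
phantomSpec <- function(imageHeight = 512, imageWidth = 512, nVertebrae = 5,
                        bodyWidth = NULL, bodyHeight = NULL, gap = NULL,
                        compressedIndex = NA, compressionFraction = 0,
                        tiltDegrees = 0, noiseSd = 8,
                        backgroundLevel = 40, bodyLevel = 200,
                        anteriorSide = c("left", "right"), seed = 1L) {
  anteriorSide <- match.arg(anteriorSide)
  stopIfNot(nVertebrae >= 3,
            "nVertebrae must be >= 3 (VCR needs two neighbours), got %d",
            nVertebrae)
  if (is.null(gap)) gap <- max(4L, round(0.035 * imageHeight))
  if (is.null(bodyHeight))
    bodyHeight <- floor((0.78 * imageHeight - (nVertebrae - 1) * gap) /
                        nVertebrae)
  if (is.null(bodyWidth)) bodyWidth <- round(0.34 * imageWidth)
  stopIfNot(compressionFraction >= 0 && compressionFraction < 1,
            "compressionFraction must be in [0, 1), got %g",
            compressionFraction)
  if (!is.na(compressedIndex)) {
    stopIfNot(compressedIndex > 1 && compressedIndex < nVertebrae,
              "compressedIndex must be interior (2..%d), got %d",
              nVertebrae - 1, compressedIndex)
  } else {
    stopIfNot(compressionFraction == 0,
              "compressionFraction > 0 requires a compressedIndex")
  }
  stopIfNot(bodyHeight >= 6 && bodyWidth >= 6,
            "vertebral bodies degenerate (bodyHeight %d, bodyWidth %d)",
            bodyHeight, bodyWidth)
  total <- nVertebrae * bodyHeight + (nVertebrae - 1) * gap
  stopIfNot(total <= imageHeight - 4,
            "column height %d px exceeds image height %d (margin 4)",
            total, imageHeight)
  stopIfNot(bodyWidth <= imageWidth - 4,
            "bodyWidth %d exceeds image width %d (margin 4)",
            bodyWidth, imageWidth)
  spec <- list(imageHeight = as.integer(imageHeight),
               imageWidth = as.integer(imageWidth),
               nVertebrae = as.integer(nVertebrae),
               bodyWidth = as.integer(bodyWidth),
               bodyHeight = as.integer(bodyHeight), gap = as.integer(gap),
               compressedIndex = as.integer(compressedIndex),
               compressionFraction = compressionFraction,
               tiltDegrees = tiltDegrees, noiseSd = noiseSd,
               backgroundLevel = backgroundLevel, bodyLevel = bodyLevel,
               anteriorSide = anteriorSide, seed = as.integer(seed))
  class(spec) <- "PhantomSpec"
  spec
}

# Exact (float) corner coordinates for every vertebra, 0-based (row, col).
# Returns 4 x 2 x n array: AS, AI, PS, PI per vertebra.
phantomCorners <- function(spec) {
  H <- spec$imageHeight; W <- spec$imageWidth
  n <- spec$nVertebrae; bh <- spec$bodyHeight; bw <- spec$bodyWidth
  total <- n * bh + (n - 1) * spec$gap
  y0 <- (H - total) / 2
  x0 <- (W - bw) / 2           # anterior (left) column
  x1 <- x0 + bw                # posterior (right) column
  corners <- array(NA_real_, c(4, 2, n),
                   dimnames = list(c("AS", "AI", "PS", "PI"),
                                   c("row", "col"), NULL))
  for (i in seq_len(n)) {
    yi <- y0 + (i - 1) * (bh + spec$gap)
    f <- if (!is.na(spec$compressedIndex) && i == spec$compressedIndex)
      spec$compressionFraction else 0
    # anterior wedging: superior endplate drops at the anterior edge,
    # posterior height preserved
    corners[, , i] <- rbind(c(yi + f * bh, x0),  # anterior-superior
                            c(yi + bh, x0),      # anterior-inferior
                            c(yi, x1),           # posterior-superior
                            c(yi + bh, x1))      # posterior-inferior
  }
  if (spec$anteriorSide == "right")
    corners[, 2, ] <- (W - 1) - corners[, 2, ]
  if (spec$tiltDegrees != 0) {
    th <- spec$tiltDegrees * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    ctr <- c((H - 1) / 2, (W - 1) / 2)
    for (i in seq_len(n))
      corners[, , i] <- sweep(sweep(corners[, , i], 2, ctr) %*% t(R), 2,
                              ctr, "+")
  }
  rng <- range(corners)
  stopIfNot(min(corners[, 1, ]) >= 0 && max(corners[, 1, ]) <= H - 1 &&
            min(corners[, 2, ]) >= 0 && max(corners[, 2, ]) <= W - 1,
            "tilted column exceeds image bounds (corner range %.1f..%.1f)",
            rng[1], rng[2])
  corners
}

# Rasterise one convex quadrilateral (corner rows AS, AI, PS, PI) onto a
# logical matrix; pixel centres at integer 0-based coordinates.
fillQuad <- function(H, W, quad) {
  poly <- quad[c("AS", "PS", "PI", "AI"), , drop = FALSE]  # cyclic order
  # normalise winding so the inside test below sees non-positive crosses
  area2 <- sum(poly[, 2] * poly[c(2:4, 1), 1] - poly[c(2:4, 1), 2] * poly[, 1])
  if (area2 < 0) poly <- poly[4:1, , drop = FALSE]
  rmin <- max(0L, floor(min(poly[, 1]))); rmax <- min(H - 1L, ceiling(max(poly[, 1])))
  cmin <- max(0L, floor(min(poly[, 2]))); cmax <- min(W - 1L, ceiling(max(poly[, 2])))
  rr <- rmin:rmax; cc <- cmin:cmax
  pr <- rep(rr, times = length(cc))
  pc <- rep(cc, each = length(rr))
  inside <- rep(TRUE, length(pr))
  for (e in 1:4) {
    a <- poly[e, ]; b <- poly[if (e == 4) 1 else e + 1, ]
    crossv <- (b[1] - a[1]) * (pc - a[2]) - (b[2] - a[2]) * (pr - a[1])
    inside <- inside & (crossv <= 1e-9)
  }
  m <- matrix(FALSE, H, W)
  m[cbind(pr[inside] + 1L, pc[inside] + 1L)] <- TRUE
  m
}

#' Generate one synthetic spine phantom
#'
#' Rasterises the vertebral column described by a [phantomSpec()] into a
#' noise-free binary mask and a noisy 8-bit image. The compressed vertebra is
#' a trapezoid whose anterior edge height is
#' \code{(1 - compressionFraction) * bodyHeight}; all other bodies are
#' rectangles. Additive Gaussian noise (sd \code{noiseSd}) is applied to the
#' image only and clipped to [0, 255]. Deterministic for a fixed seed.
#'
#' @param spec a [phantomSpec()].
#' @return A \linkS4class{PhantomSample}.
#' @examples
#' s <- generatePhantom(phantomSpec(imageHeight = 128, imageWidth = 128,
#'                                  compressedIndex = 3,
#'                                  compressionFraction = 0.4))
#' trueVCR(s)
#' @export
generatePhantom <- function(spec) {
  stopIfNot(inherits(spec, "PhantomSpec"),
            "spec must be created by phantomSpec()")
  H <- spec$imageHeight; W <- spec$imageWidth
  corners <- phantomCorners(spec)
  mask <- matrix(FALSE, H, W)
  for (i in seq_len(spec$nVertebrae))
    mask <- mask | fillQuad(H, W, corners[, , i])
  maskInt <- matrix(as.integer(mask), H, W)
  img <- spec$backgroundLevel + (spec$bodyLevel - spec$backgroundLevel) *
    maskInt
  if (spec$noiseSd > 0) {
    noise <- withSeed(spec$seed, rnorm(H * W, sd = spec$noiseSd))
    img <- img + matrix(noise, H, W)
  }
  img <- matrix(clip8bit(img), H, W)
  new("PhantomSample", image = img, mask = maskInt,
      trueVcrPercent = 100 * spec$compressionFraction,
      compressedIndex = spec$compressedIndex, cornerTruth = corners,
      spec = unclass(spec))
}

#' Generate a dataset of phantoms with varying compression and geometry
#'
#' Draws \code{nSamples} phantoms from a template spec: the compression
#' fraction is uniform over \code{compressionRange}, the compressed level is
#' chosen uniformly among interior vertebrae, and (optionally) body size,
#' gap and tilt are jittered per sample. Each sample carries its own ground
#' truth and derived child seed, so the dataset is reproducible from
#' (template, nSamples, seed) alone.
#'
#' @param template a [phantomSpec()] used as the base geometry.
#' @param nSamples number of phantoms (>= 1).
#' @param seed master seed; per-sample seeds are derived from it.
#' @param compressionRange length-2 numeric; uniform range for the
#'   compression fraction. Use \code{c(0, 0)} for an uncompressed dataset.
#' @param jitter logical; jitter body size (+/- 8%), gap and tilt (+/- 4 deg)
#'   per sample.
#' @return A list of \linkS4class{PhantomSample} objects.
#' @examples
#' ds <- generatePhantomDataset(phantomSpec(imageHeight = 128,
#'                                          imageWidth = 128),
#'                              nSamples = 3, seed = 7)
#' sapply(ds, trueVCR)
#' @export
generatePhantomDataset <- function(template, nSamples, seed = 1L,
                                   compressionRange = c(0.1, 0.5),
                                   jitter = TRUE) {
  stopIfNot(nSamples >= 1, "nSamples must be >= 1, got %d", nSamples)
  stopIfNot(length(compressionRange) == 2 &&
            compressionRange[1] <= compressionRange[2] &&
            compressionRange[1] >= 0 && compressionRange[2] < 1,
            "compressionRange must be an ordered pair within [0, 1)")
  draws <- withSeed(seed, {
    list(frac = runif(nSamples, compressionRange[1], compressionRange[2]),
         level = sample(seq(2L, template$nVertebrae - 1L), nSamples,
                        replace = TRUE),
         jbw = runif(nSamples, 0.92, 1.08),
         jbh = runif(nSamples, 0.92, 1.08),
         jtilt = runif(nSamples, -4, 4))
  })
  lapply(seq_len(nSamples), function(i) {
    frac <- draws$frac[i]
    sp <- template
    if (jitter) {
      sp$bodyWidth <- as.integer(round(template$bodyWidth * draws$jbw[i]))
      sp$bodyHeight <- as.integer(round(template$bodyHeight * draws$jbh[i]))
      sp$tiltDegrees <- template$tiltDegrees + draws$jtilt[i]
    }
    sp$compressionFraction <- frac
    sp$compressedIndex <- if (frac > 0) draws$level[i] else NA_integer_
    sp$seed <- childSeed(seed, i)
    # re-validate the jittered geometry through the constructor
    spec <- phantomSpec(sp$imageHeight, sp$imageWidth, sp$nVertebrae,
                        sp$bodyWidth, sp$bodyHeight, sp$gap,
                        sp$compressedIndex, sp$compressionFraction,
                        sp$tiltDegrees, sp$noiseSd, sp$backgroundLevel,
                        sp$bodyLevel, sp$anteriorSide, sp$seed)
    generatePhantom(spec)
  })
}

#' Write a phantom dataset to disk
#'
#' Writes paired files \code{<stem>_img.png} (8-bit grayscale) and
#' \code{<stem>_mask.png} (0/255 binary) per sample plus a
#' \code{manifest.csv} with the per-sample ground truth.
#'
#' @param samples list of \linkS4class{PhantomSample}.
#' @param dir output directory (created if needed).
#' @param prefix file-stem prefix, default \code{"phantom"}.
#' @return Invisibly, the manifest data.frame.
#' @export
writePhantomDataset <- function(samples, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    stem <- sprintf("%s_%04d", prefix, i)
    png::writePNG(phantomImage(s) / 255, file.path(dir,
                                                   paste0(stem, "_img.png")))
    png::writePNG(phantomMask(s) + 0, file.path(dir,
                                                paste0(stem, "_mask.png")))
    data.frame(sample = stem, trueVcrPercent = trueVCR(s),
               compressedIndex = compressedIndex(s), seed = s@spec$seed,
               image = paste0(stem, "_img.png"),
               mask = paste0(stem, "_mask.png"))
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
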