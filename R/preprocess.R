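#' Pre-processing configuration
#'
#' Parameters of the radiograph normalisation chain: 16-to-8-bit percentile
#' rescale, CLAHE, Gaussian denoising, and the aspect-preserving
#' resize-and-zero-pad to the model input size.
#'
#' @param targetSize length-2 integer (rows, cols), default \code{c(512, 512)}.
#' @param claheClipLimit CLAHE clip limit (dimensionless), default 2.
#' @param claheTileGrid length-2 integer (rows, cols) of CLAHE tiles,
#'   default \code{c(8, 8)}.
#' @param gaussianSigma Gaussian smoothing sigma in pixels (0 disables),
#'   default 1.
#' @param rescalePercentiles length-2 numeric (low, high) percentiles for the
#'   16-to-8-bit linear rescale, default \code{c(0.5, 99.5)} (robust to
#'   detector outlier pixels).
#' @return A validated list of class \code{"PreprocConfig"}.
#' @export
preprocConfig <- function(targetSize = c(512L, 512L), claheClipLimit = 2,
                          claheTileGrid = c(8L, 8L), gaussianSigma = 1,
                          rescalePercentiles = c(0.5, 99.5)) {
  stopIfNot(length(targetSize) == 2 && all(targetSize >= 1),
            "targetSize must be two positive integers")
  p <- rescalePercentiles
  stopIfNot(length(p) == 2 && p[1] >= 0 && p[1] < p[2] && p[2] <= 100,
            "rescalePercentiles must satisfy 0 <= low < high <= 100")
  stopIfNot(gaussianSigma >= 0, "gaussianSigma must be >= 0")
  cfg <- list(targetSize = as.integer(targetSize),
              claheClipLimit = claheClipLimit,
              claheTileGrid = as.integer(claheTileGrid),
              gaussianSigma = gaussianSigma,
              rescalePercentiles = as.numeric(p))
  class(cfg) <- "PreprocConfig"
  cfg
}

#' Reduce a radiograph to 8-bit
#'
#' 16-bit inputs are linearly rescaled between the configured intensity
#' percentiles and clipped to [0, 255]; 8-bit inputs pass through unchanged.
#' A constant image has a degenerate percentile window and is rejected.
#'
#' @param rec a \linkS4class{Radiograph}.
#' @param cfg a [preprocConfig()].
#' @return An 8-bit \linkS4class{Radiograph}.
#' @export
to8bit <- function(rec, cfg = preprocConfig()) {
  stopIfNot(is(rec, "Radiograph"), "rec must be a Radiograph")
  if (bitDepth(rec) == 8L) return(rec)
  px <- pixels(rec)
  q <- quantile(px, cfg$rescalePercentiles / 100, names = FALSE)
  stopIfNot(q[2] > q[1],
            "degenerate percentile window [%g, %g]: image is constant %s",
            q[1], q[2], "over the configured percentiles")
  out <- (px - q[1]) / (q[2] - q[1]) * 255
  out <- clip8bit(out)
  Radiograph(out, bitDepth = 8L, pixelSpacing = pixelSpacing(rec),
             sourceId = rec@sourceId)
}

# Matrix (rows x cols) <-> EBImage (x = cols, y = rows) wrappers.
asEBI <- function(px) EBImage::Image(t(px))
fromEBI <- function(img) t(EBImage::imageData(img))

#' Contrast enhancement: CLAHE followed by Gaussian denoising
#'
#' Applies contrast-limited adaptive histogram equalisation first and a
#' Gaussian filter second; the output remains 8-bit. With
#' \code{gaussianSigma = 0} the smoothing step is a no-op.
#'
#' @inheritParams to8bit
#' @return An 8-bit \linkS4class{Radiograph} with enhanced contrast.
#' @export
enhanceRadiograph <- function(rec, cfg = preprocConfig()) {
  stopIfNot(is(rec, "Radiograph") && bitDepth(rec) == 8L,
            "enhanceRadiograph expects an 8-bit Radiograph; run to8bit first")
  px <- pixels(rec)
  if (sd(px) > 0) {
    # CLAHE tiles must divide the image size: replicate edges up to the
    # next multiple, equalise, then crop back
    tiles <- cfg$claheTileGrid
    H <- nrow(px); W <- ncol(px)
    padH <- (tiles[1] - H %% tiles[1]) %% tiles[1]
    padW <- (tiles[2] - W %% tiles[2]) %% tiles[2]
    work <- px[c(seq_len(H), rep(H, padH)), c(seq_len(W), rep(W, padW))]
    img <- EBImage::clahe(asEBI(work / 255), nx = tiles[2], ny = tiles[1],
                          limit = cfg$claheClipLimit)
    px <- (fromEBI(img) * 255)[seq_len(H), seq_len(W)]
  }
  if (cfg$gaussianSigma > 0)
    px <- fromEBI(EBImage::gblur(asEBI(px), sigma = cfg$gaussianSigma))
  px <- clip8bit(px)
  Radiograph(px, bitDepth = 8L, pixelSpacing = pixelSpacing(rec),
             sourceId = rec@sourceId)
}

#' Aspect-preserving resize with symmetric zero padding
#'
#' Scales the image by a single factor so the longer side matches the target,
#' then pads symmetrically with zeros (split floor/ceil when odd) to exactly
#' \code{targetSize}. Returns the padded image together with the
#' \linkS4class{GeomTransform} that maps original to padded coordinates.
#'
#' @inheritParams to8bit
#' @return list with elements \code{record} (padded 8-bit
#'   \linkS4class{Radiograph}) and \code{transform}
#'   (\linkS4class{GeomTransform}).
#' @export
resizeAndPad <- function(rec, cfg = preprocConfig()) {
  stopIfNot(is(rec, "Radiograph") && bitDepth(rec) == 8L,
            "resizeAndPad expects an 8-bit Radiograph")
  px <- pixels(rec)
  H <- nrow(px); W <- ncol(px)
  stopIfNot(H >= 1 && W >= 1, "zero-sized input image")
  tr <- cfg$targetSize[1]; tc <- cfg$targetSize[2]
  scale <- min(tr / H, tc / W)
  newH <- max(1L, as.integer(floor(H * scale + 1e-9)))
  newW <- max(1L, as.integer(floor(W * scale + 1e-9)))
  content <- if (newH == H && newW == W) px else
    fromEBI(EBImage::resize(asEBI(px / 255), w = newW, h = newH,
                            antialias = FALSE)) * 255
  content <- clip8bit(content)
  padTop <- (tr - newH) %/% 2L
  padLeft <- (tc - newW) %/% 2L
  out <- matrix(0, tr, tc)
  out[padTop + seq_len(newH), padLeft + seq_len(newW)] <- content
  tf <- GeomTransform(scale, c(padTop, padLeft), c(H, W))
  list(record = Radiograph(out, 8L, pixelSpacing(rec), rec@sourceId),
       transform = tf)
}

#' Map coordinates between the original and padded frames
#'
#' Coordinates are 0-based (row, col) pixel centres. The forward map is
#' \code{padded = original * scale + pad}; the inverse map undoes it exactly,
#' so round trips are lossless.
#'
#' @param points numeric matrix n x 2 of (row, col) coordinates (a length-2
#'   vector is accepted for a single point).
#' @param transform a \linkS4class{GeomTransform}.
#' @return numeric matrix n x 2 of mapped coordinates.
#' @examples
#' tf <- GeomTransform(0.5, c(0, 64), c(1024, 768))
#' inverseMapPoints(c(100, 164), tf)  # -> (200, 200)
#' @export
forwardMapPoints <- function(points, transform) {
  p <- asPointMatrix(points)
  sweep(p * transform@scale, 2, transform@padOffset, "+")
}

#' @rdname forwardMapPoints
#' @export
inverseMapPoints <- function(points, transform) {
  p <- asPointMatrix(points)
  sweep(p, 2, transform@padOffset, "-") / transform@scale
}

asPointMatrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2, byrow = TRUE)
  stopIfNot(ncol(points) == 2, "points must be (row, col) pairs")
  points
}

#' Convert a pixel distance to millimetres
#'
#' Distances measured in the padded model frame are first divided by the
#' transform scale (back to original-image pixels), then multiplied by the
#' mean of the row/col pixel spacing.
#'
#' @param distPx distance in padded-frame pixels.
#' @param transform a \linkS4class{GeomTransform} (or NULL for none).
#' @param spacingMm length-2 (row, col) pixel spacing in mm.
#' @return distance in mm.
#' @export
pixelDistanceMm <- function(distPx, transform = NULL, spacingMm) {
  stopIfNot(length(spacingMm) == 2 && all(spacingMm > 0),
            "spacingMm must be two positive values")
  orig <- if (is.null(transform)) distPx else distPx / transform@scale
  orig * mean(spacingMm)
}

#' Full pre-processing chain
#'
#' Bit-depth reduction, CLAHE, Gaussian denoising, then aspect-preserving
#' resize and zero padding, in that order. The output is always exactly
#' \code{targetSize} and 8-bit; the returned transform maps original
#' coordinates into the padded frame.
#'
#' @inheritParams to8bit
#' @return list with \code{record} and \code{transform} as in
#'   [resizeAndPad()].
#' @export
preprocessRadiograph <- function(rec, cfg = preprocConfig()) {
  rec <- to8bit(rec, cfg)
  rec <- enhanceRadiograph(rec, cfg)
  resizeAndPad(rec, cfg)
}

#' Read a radiograph from PNG or DICOM
#'
#' PNG files are read with \pkg{png} (values rescaled to 8-bit; RGB inputs
#' are averaged to grayscale). Files with a \code{.dcm} extension (or a DICM
#' magic marker) are read with the built-in single-frame DICOM reader, which
#' extracts bit depth, pixel spacing and photometric interpretation
#' (MONOCHROME1 is inverted to MONOCHROME2 convention).
#'
#' @param path file path.
#' @return A \linkS4class{Radiograph}.
#' @export
readRadiograph <- function(path) {
  stopIfNot(file.exists(path), "file not found: %s", path)
  if (isDicomFile(path)) return(readDicomImage(path))
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3])], c(1, 2),
                                      mean)
  Radiograph(round(a * 255), bitDepth = 8L,
             sourceId = sub("\\.[^.]*$", "", basename(path)))
}

#' Write an 8-bit radiograph or mask as PNG
#'
#' @param x a \linkS4class{Radiograph}, or a numeric matrix (masks are
#'   written as 0/255).
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeImagePNG <- function(x, path) {
  px <- if (is(x, "Radiograph")) pixels(x) else x
  if (all(px %in% c(0, 1))) px <- px * 255
  png::writePNG(clip8bit(px) / 255, path)
  invisible(path)
}
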