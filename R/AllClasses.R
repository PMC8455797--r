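#' Radiograph: a single-frame grayscale spine image
#'
#' Container for one lateral spine radiograph: the pixel matrix, its declared
#' bit depth (8 or 16), optional physical pixel spacing in mm, and a source
#' identifier. Pixel values are stored as a numeric matrix in image row/column
#' order; values must lie within the declared bit depth.
#'
#' @slot pixels numeric matrix of grayscale values (rows x cols).
#' @slot bitDepth integer, 8 or 16.
#' @slot pixelSpacing numeric of length 0 (unknown) or 2: (row, col) spacing
#'   in millimetres, strictly positive.
#' @slot sourceId character identifier (file stem or accession).
#' @export
setClass("Radiograph",
  representation(pixels = "matrix", bitDepth = "integer",
                 pixelSpacing = "numeric", sourceId = "character"),
  prototype(bitDepth = 8L, pixelSpacing = numeric(0), sourceId = ""))

setValidity("Radiograph", function(object) {
  px <- object@pixels
  if (!is.numeric(px) || length(dim(px)) != 2L)
    return("pixels must be a 2-d numeric matrix")
  if (!object@bitDepth %in% c(8L, 16L))
    return("bitDepth must be 8 or 16")
  if (any(!is.finite(px)))
    return("pixels must be finite")
  if (min(px) < 0 || max(px) > 2^object@bitDepth - 1)
    return(sprintf("pixel values outside [0, %d] for declared bit depth",
                   2^object@bitDepth - 1))
  sp <- object@pixelSpacing
  if (length(sp) && (length(sp) != 2L || any(sp <= 0)))
    return("pixelSpacing must be two strictly positive values (row, col) mm")
  TRUE
})

#' Construct a Radiograph
#'
#' @param pixels numeric matrix of grayscale values.
#' @param bitDepth 8 or 16.
#' @param pixelSpacing optional numeric length-2 (row, col) spacing in mm.
#' @param sourceId identifier string.
#' @return A \linkS4class{Radiograph}.
#' @examples
#' r <- Radiograph(matrix(0:255, 16, 16), bitDepth = 8)
#' dim(pixels(r))
#' @export
Radiograph <- function(pixels, bitDepth = 8L, pixelSpacing = numeric(0),
                       sourceId = "") {
  new("Radiograph", pixels = pixels, bitDepth = as.integer(bitDepth),
      pixelSpacing = as.numeric(pixelSpacing), sourceId = sourceId)
}

#' GeomTransform: invertible record of the resize-and-pad geometry
#'
#' Records the single isotropic scale factor and the (row, col) zero-padding
#' offsets applied when an image is resized and padded to the model input
#' size, so that landmark coordinates measured in the padded frame can be
#' mapped back to original-image pixels (and to mm when pixel spacing is
#' known). Coordinates are 0-based (row, col) pixel centres; the forward map
#' is \code{padded = original * scale + pad}.
#'
#' @slot scale numeric scalar > 0.
#' @slot padOffset numeric length-2 (row, col) padding of the top-left corner.
#' @slot originalSize integer length-2 (rows, cols) of the source image.
#' @export
setClass("GeomTransform",
  representation(scale = "numeric", padOffset = "numeric",
                 originalSize = "integer"))

setValidity("GeomTransform", function(object) {
  if (length(object@scale) != 1L || object@scale <= 0)
    return("scale must be a single positive number")
  if (length(object@padOffset) != 2L || any(object@padOffset < 0))
    return("padOffset must be two non-negative values (row, col)")
  if (length(object@originalSize) != 2L || any(object@originalSize < 1L))
    return("originalSize must be two positive integers")
  TRUE
})

GeomTransform <- function(scale, padOffset, originalSize) {
  new("GeomTransform", scale = as.numeric(scale),
      padOffset = as.numeric(padOffset),
      originalSize = as.integer(originalSize))
}

#' PhantomSample: one synthetic lateral-spine image with ground truth
#'
#' A generated phantom: the noisy 8-bit image, its noise-free binary mask,
#' the true compression ratio implied by the construction, and the exact
#' (pre-rasterisation) corner landmarks of every vertebral body.
#'
#' @slot image integer-valued numeric matrix in [0, 255].
#' @slot mask binary (0/1) integer matrix, same shape.
#' @slot trueVcrPercent numeric; 100 x compression fraction (0 if none).
#' @slot compressedIndex integer index (1-based, craniocaudal) of the
#'   compressed vertebra, or NA when none.
#' @slot cornerTruth numeric array 4 x 2 x nVertebrae: rows are
#'   anterior-superior, anterior-inferior, posterior-superior,
#'   posterior-inferior; columns are 0-based (row, col) coordinates.
#' @slot spec list; the generating specification.
#' @export
setClass("PhantomSample",
  representation(image = "matrix", mask = "matrix",
                 trueVcrPercent = "numeric", compressedIndex = "integer",
                 cornerTruth = "array", spec = "list"))

setValidity("PhantomSample", function(object) {
  if (!identical(dim(object@image), dim(object@mask)))
    return("image and mask must share dimensions")
  if (!all(object@mask %in% c(0L, 1L)))
    return("mask must be binary 0/1")
  if (object@trueVcrPercent < 0 || object@trueVcrPercent >= 100)
    return("trueVcrPercent must be in [0, 100)")
  TRUE
})

#' MDR2UNet: the segmentation model
#'
#' A U-shaped encoder-decoder whose first encoder stage is a multi-dilated
#' residual block (parallel dilated convolutions concatenated then reduced by
#' a 1x1 bottleneck, with a shortcut) and whose remaining stages are
#' recurrent residual blocks (a weight-shared convolution applied for a fixed
#' number of steps with feature accumulation, wrapped in a shortcut).
#' Parameters live in an environment so training updates in place.
#'
#' @slot config list; see [modelConfig()].
#' @slot net environment holding the layer graph and parameters.
#' @export
setClass("MDR2UNet",
  representation(config = "list", net = "environment"))

#' VCRReport: per-level vertebral compression ratios for one mask
#'
#' @slot instances data.frame with one row per vertebra in craniocaudal
#'   order: label, centroidRow, centroidCol, area, anteriorHeight (px in the
#'   measured frame), anteriorHeightOrig (original-frame px, when a transform
#'   is supplied) and anteriorHeightMm (when spacing is known).
#' @slot corners numeric array 4 x 2 x n of corner landmarks (0-based
#'   row/col) in the measured frame.
#' @slot results data.frame with one row per interior vertebra: levelIndex,
#'   v1, v2, v3 (anterior heights), vcrPercent, grade.
#' @slot flagged integer; levelIndex with the maximum VCR.
#' @slot spacingMm numeric length 0 or 2.
#' @export
setClass("VCRReport",
  representation(instances = "data.frame", corners = "array",
                 results = "data.frame", flagged = "integer",
                 spacingMm = "numeric"))

setValidity("VCRReport", function(object) {
  n <- nrow(object@instances)
  if (n >= 3L && nrow(object@results) != n - 2L)
    return("results must cover exactly the interior vertebrae (n - 2 rows)")
  TRUE
})
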