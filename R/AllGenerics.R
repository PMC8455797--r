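#' Accessors for SpineVCR classes
#'
#' Small accessor generics so downstream code never touches slots directly:
#' \code{pixels}/\code{bitDepth}/\code{pixelSpacing} for
#' \linkS4class{Radiograph}; \code{phantomImage}/\code{phantomMask}/
#' \code{trueVCR}/\code{cornerTruth} for \linkS4class{PhantomSample};
#' \code{vcrResults}/\code{vertebraTable}/\code{flaggedLevel} for
#' \linkS4class{VCRReport}.
#'
#' @param x the object.
#' @return The slot content (matrix, numeric, data.frame or array).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "Radiograph", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))
#' @rdname accessors
#' @export
setMethod("bitDepth", "Radiograph", function(x) x@bitDepth)

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "Radiograph", function(x) x@pixelSpacing)

#' @rdname accessors
#' @export
setGeneric("phantomImage", function(x) standardGeneric("phantomImage"))
#' @rdname accessors
#' @export
setMethod("phantomImage", "PhantomSample", function(x) x@image)

#' @rdname accessors
#' @export
setGeneric("phantomMask", function(x) standardGeneric("phantomMask"))
#' @rdname accessors
#' @export
setMethod("phantomMask", "PhantomSample", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("trueVCR", function(x) standardGeneric("trueVCR"))
#' @rdname accessors
#' @export
setMethod("trueVCR", "PhantomSample", function(x) x@trueVcrPercent)

#' @rdname accessors
#' @export
setGeneric("cornerTruth", function(x) standardGeneric("cornerTruth"))
#' @rdname accessors
#' @export
setMethod("cornerTruth", "PhantomSample", function(x) x@cornerTruth)

#' @rdname accessors
#' @export
setGeneric("compressedIndex", function(x) standardGeneric("compressedIndex"))
#' @rdname accessors
#' @export
setMethod("compressedIndex", "PhantomSample", function(x) x@compressedIndex)

#' @rdname accessors
#' @export
setGeneric("vcrResults", function(x) standardGeneric("vcrResults"))
#' @rdname accessors
#' @export
setMethod("vcrResults", "VCRReport", function(x) x@results)

#' @rdname accessors
#' @export
setGeneric("vertebraTable", function(x) standardGeneric("vertebraTable"))
#' @rdname accessors
#' @export
setMethod("vertebraTable", "VCRReport", function(x) x@instances)

#' @rdname accessors
#' @export
setGeneric("flaggedLevel", function(x) standardGeneric("flaggedLevel"))
#' @rdname accessors
#' @export
setMethod("flaggedLevel", "VCRReport", function(x) x@flagged)

#' @rdname accessors
#' @export
setGeneric("modelConfigOf", function(x) standardGeneric("modelConfigOf"))
#' @rdname accessors
#' @export
setMethod("modelConfigOf", "MDR2UNet", function(x) x@config)

setMethod("show", "Radiograph", function(object) {
  d <- dim(object@pixels)
  sp <- if (length(object@pixelSpacing))
    sprintf("%.3f x %.3f mm", object@pixelSpacing[1], object@pixelSpacing[2])
  else "unknown"
  cat(sprintf("Radiograph '%s': %d x %d, %d-bit, spacing %s\n",
              object@sourceId, d[1], d[2], object@bitDepth, sp))
})

setMethod("show", "GeomTransform", function(object) {
  cat(sprintf(
    "GeomTransform: scale %.4f, pad (%g, %g), original %d x %d\n",
    object@scale, object@padOffset[1], object@padOffset[2],
    object@originalSize[1], object@originalSize[2]))
})

setMethod("show", "PhantomSample", function(object) {
  d <- dim(object@image)
  cat(sprintf(
    "PhantomSample: %d x %d, %d vertebrae, true VCR %.1f%%%s\n",
    d[1], d[2], dim(object@cornerTruth)[3], object@trueVcrPercent,
    if (is.na(object@compressedIndex)) ""
    else sprintf(" at level %d", object@compressedIndex)))
})

setMethod("show", "MDR2UNet", function(object) {
  cfg <- object@config
  cat(sprintf(
    "MDR2UNet: depth %d, base filters %d, input %d x %d\n",
    cfg$depth, cfg$baseFilters, cfg$inputSize[1], cfg$inputSize[2]))
  cat(sprintf("  dilation rates: %s; recurrence steps: %d; parameters: %d\n",
              paste(cfg$dilationRates, collapse = ", "),
              cfg$recurrenceSteps, modelParameterCount(object)))
})

setMethod("show", "VCRReport", function(object) {
  cat(sprintf("VCRReport: %d vertebrae, %d interior levels\n",
              nrow(object@instances), nrow(object@results)))
  if (nrow(object@results)) {
    print(object@results, digits = 4)
    cat(sprintf("flagged level: %d (max VCR %.1f%%)\n", object@flagged,
                max(object@results$vcrPercent)))
  }
})
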