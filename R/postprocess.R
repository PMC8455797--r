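#' Post-processing configuration
#'
#' Controls the two mask clean-up rules: removal of under-sized connected
#' components (miss-detections) and filling of interior background pixels
#' whose full 8-neighbourhood is foreground. The area threshold is
#' scale-free by default: a fraction of the median component area.
#'
#' @param minArea area threshold. In \code{"fraction"} mode this is the
#'   fraction of the median component area (default 0.2); in
#'   \code{"absolute"} mode it is a pixel count.
#' @param areaMode \code{"fraction"} or \code{"absolute"}.
#' @param fillMode \code{"strict8"} applies the literal rule (a background
#'   pixel becomes foreground only when all 8 neighbours are foreground);
#'   \code{"flood"} additionally closes any enclosed hole via
#'   border-connected flood fill. Strict mode cannot close holes wider than
#'   one pixel (each pixel of a 2x2 hole has hole neighbours).
#' @param maxFillIterations iteration cap for strict mode; \code{Inf} means
#'   iterate to convergence, 1 gives a single pass.
#' @return A validated list of class \code{"PostprocConfig"}.
#' @export
postprocConfig <- function(minArea = 0.2,
                           areaMode = c("fraction", "absolute"),
                           fillMode = c("strict8", "flood"),
                           maxFillIterations = Inf) {
  areaMode <- match.arg(areaMode)
  fillMode <- match.arg(fillMode)
  stopIfNot(minArea >= 0, "minArea must be >= 0")
  stopIfNot(maxFillIterations >= 1, "maxFillIterations must be >= 1")
  cfg <- list(minArea = minArea, areaMode = areaMode, fillMode = fillMode,
              maxFillIterations = maxFillIterations)
  class(cfg) <- "PostprocConfig"
  cfg
}

#' Label 8-connected components of a binary mask
#'
#' @param mask binary matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
labelComponents <- function(mask) {
  .label8(asBinaryMask(mask))
}

#' Remove under-sized connected components
#'
#' Components (8-connectivity) with area below the threshold are deemed
#' miss-detections and set to background; all others are untouched. In
#' fractional mode the threshold is \code{minArea} times the median
#' component area.
#'
#' @param mask binary matrix.
#' @param cfg a [postprocConfig()].
#' @return binary 0/1 integer matrix.
#' @examples
#' m <- matrix(0L, 8, 8); m[2:5, 2:5] <- 1L; m[8, 8] <- 1L
#' sum(removeSmall(m, postprocConfig(10, "absolute")))
#' @export
removeSmall <- function(mask, cfg = postprocConfig()) {
  mask <- asBinaryMask(mask)
  lab <- .label8(mask)
  ncomp <- max(lab)
  if (ncomp == 0) return(mask)
  areas <- tabulate(lab[lab > 0], nbins = ncomp)
  thr <- if (cfg$areaMode == "fraction") cfg$minArea * median(areas)
         else cfg$minArea
  drop <- which(areas < thr)
  if (length(drop)) mask[lab %in% drop] <- 0L
  mask
}

#' Fill interior holes of a binary mask
#'
#' Strict mode applies the literal 8-neighbourhood rule iteratively until no
#' pixel changes (or \code{maxFillIterations}): a background pixel becomes
#' foreground when all eight of its neighbours are foreground. This fills
#' single-pixel voids but, by construction, leaves holes of width >= 2
#' untouched (every pixel of a 2x2 hole has at least one background
#' neighbour). Flood mode closes any hole not connected to the image border.
#'
#' @inheritParams removeSmall
#' @return binary 0/1 integer matrix.
#' @export
fillHoles <- function(mask, cfg = postprocConfig()) {
  mask <- asBinaryMask(mask)
  if (cfg$fillMode == "flood") {
    filled <- EBImage::fillHull(EBImage::Image(t(mask)))
    return(matrix(as.integer(t(EBImage::imageData(filled)) > 0),
                  nrow(mask), ncol(mask)))
  }
  H <- nrow(mask); W <- ncol(mask)
  iter <- 0
  repeat {
    iter <- iter + 1
    # pad with background so border pixels never qualify
    p <- matrix(0L, H + 2, W + 2)
    p[2:(H + 1), 2:(W + 1)] <- mask
    nb <- p[1:H, 1:W] + p[1:H, 2:(W + 1)] + p[1:H, 3:(W + 2)] +
          p[2:(H + 1), 1:W] + p[2:(H + 1), 3:(W + 2)] +
          p[3:(H + 2), 1:W] + p[3:(H + 2), 2:(W + 1)] + p[3:(H + 2), 3:(W + 2)]
    fill <- mask == 0L & nb == 8L
    if (!any(fill) || iter > cfg$maxFillIterations) break
    mask[fill] <- 1L
    if (iter >= cfg$maxFillIterations) break
  }
  mask
}

#' Clean a predicted mask
#'
#' [removeSmall()] then [fillHoles()], in that order (filling first could
#' promote specks above the area threshold), iterated to a fixed point:
#' filling can raise the fractional area threshold for the next pass, so a
#' single pass is not always stable, while the fixed point is idempotent by
#' construction. In practice the first pass already converges and the second
#' merely verifies it.
#'
#' @inheritParams removeSmall
#' @return binary 0/1 integer matrix.
#' @export
cleanMask <- function(mask, cfg = postprocConfig()) {
  mask <- asBinaryMask(mask)
  repeat {
    out <- fillHoles(removeSmall(mask, cfg), cfg)
    if (identical(out, mask)) return(out)
    mask <- out
  }
}
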