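# Vertebral compression ratio geometry: instance separation, corner
# landmarks, the VCR formula and severity grading.

#' Separate and order vertebral bodies in a cleaned mask
#'
#' Extracts 8-connected components and orders them craniocaudally by
#' projecting component centroids onto the first principal axis of the
#' centroid cloud (the spine axis). The axis is oriented so that increasing
#' projection means increasing image row; ordering is therefore tolerant to
#' a tilted column. At least three components are required, because the
#' compression ratio of a level needs both neighbours.
#'
#' @param mask binary matrix (ideally after [cleanMask()]).
#' @return list with \code{instances} (list of per-vertebra records: label,
#'   pixels as 0-based (row, col) matrix, centroid, area, in craniocaudal
#'   order) and \code{axis} (unit spine-axis vector, superior to inferior).
#' @export
separateInstances <- function(mask) {
  mask <- asBinaryMask(mask)
  lab <- .label8(mask)
  ncomp <- max(lab)
  stopIfNot(ncomp >= 3,
            "found %d vertebral components but VCR needs at least 3 %s",
            ncomp, "(a level and both neighbours)")
  inst <- lapply(seq_len(ncomp), function(k) {
    w <- which(lab == k)
    rows <- (w - 1L) %% nrow(mask)        # 0-based coordinates
    cols <- (w - 1L) %/% nrow(mask)
    ord <- order(rows, cols)              # lexicographic for tie-breaking
    px <- cbind(row = rows[ord], col = cols[ord])
    list(label = k, pixels = px,
         centroid = c(mean(px[, 1]), mean(px[, 2])), area = nrow(px))
  })
  cent <- do.call(rbind, lapply(inst, `[[`, "centroid"))
  pc <- prcomp(cent, center = TRUE, scale. = FALSE)
  axis <- pc$rotation[, 1]
  if (axis[1] < 0) axis <- -axis          # point superior -> inferior (+row)
  proj <- as.numeric(cent %*% axis)
  list(instances = inst[order(proj)], axis = axis / sqrt(sum(axis^2)))
}

#' Locate the four corner landmarks of one vertebral body
#'
#' In the instance's local frame (spine axis = superior-inferior, orthogonal
#' = anterior-posterior with the anterior sign set by \code{anteriorSide}),
#' each corner is the pixel maximising the corresponding signed combination
#' of the two projections; ties resolve to the lexicographically smallest
#' (row, col). The anterior height is the Euclidean distance between the two
#' anterior corners plus one pixel (centre-to-centre distances undercount
#' the physical extent by half a pixel at each endplate).
#'
#' @param inst one instance record from [separateInstances()].
#' @param anteriorSide \code{"left"} or \code{"right"}.
#' @param spineAxis unit (row, col) vector of the craniocaudal axis.
#' @param minArea reject degenerate components below this pixel count.
#' @return list with \code{corners} (4 x 2 matrix, rows AS, AI, PS, PI, in
#'   0-based (row, col)) and \code{anteriorHeight} in pixels.
#' @export
findCorners <- function(inst, anteriorSide = c("left", "right"),
                        spineAxis = c(1, 0), minArea = 12) {
  anteriorSide <- match.arg(anteriorSide)
  stopIfNot(inst$area >= minArea,
            "degenerate component (area %d < %g)", inst$area, minArea)
  u <- spineAxis / sqrt(sum(spineAxis^2))
  v <- c(-u[2], u[1])                     # orthogonal, in-plane
  wantNegCol <- anteriorSide == "left"
  if ((v[2] < 0) != wantNegCol) v <- -v   # v points anterior
  px <- inst$pixels
  pu <- px[, 1] * u[1] + px[, 2] * u[2]
  pv <- px[, 1] * v[1] + px[, 2] * v[2]
  rng <- (max(pu) - min(pu)) * (max(pv) - min(pv))
  stopIfNot(rng > 1,
            "degenerate (line-like) component: no 2-d extent for corners")
  pick <- function(su, sv) px[which.max(su * pu + sv * pv), ]
  corners <- rbind(AS = pick(-1, +1), AI = pick(+1, +1),
                   PS = pick(-1, -1), PI = pick(+1, -1))
  colnames(corners) <- c("row", "col")
  d <- corners["AS", ] - corners["AI", ]
  list(corners = corners, anteriorHeight = sqrt(sum(d^2)) + 1)
}

#' Vertebral compression ratio of one level
#'
#' \code{VCR = (1 - v2 / ((v1 + v3) / 2)) * 100} where \code{v2} is the
#' anterior height of the index vertebra and \code{v1}, \code{v3} those of
#' its cranial and caudal neighbours. Negative values (index taller than the
#' neighbour mean) are reported as-is, never clamped.
#'
#' @param v1,v3 neighbour anterior heights (> 0).
#' @param v2 index anterior height (>= 0).
#' @return VCR in percent.
#' @examples
#' computeVCR(28, 21, 32)  # 30
#' @export
computeVCR <- function(v1, v2, v3) {
  stopIfNot(all(v1 + v3 > 0), "neighbour heights must not both be zero")
  stopIfNot(all(v1 > 0) && all(v3 > 0) && all(v2 >= 0),
            "heights must be positive (v2 may be zero)")
  (1 - v2 / ((v1 + v3) / 2)) * 100
}

#' Severity grade of a compression ratio
#'
#' Left-closed intervals on configurable cut points; the defaults follow the
#' conventional semiquantitative fracture grading: below 20 percent no
#' fracture, 20-25 mild, 25-40 moderate, 40 and above severe.
#'
#' @param vcrPercent finite VCR value(s) in percent.
#' @param cuts increasing length-3 numeric cut points.
#' @return factor with levels none, mild, moderate, severe.
#' @examples
#' gradeVCR(c(0, 25, 50))
#' @export
gradeVCR <- function(vcrPercent, cuts = c(20, 25, 40)) {
  stopIfNot(all(is.finite(vcrPercent)), "VCR must be finite")
  stopIfNot(length(cuts) == 3 && all(diff(cuts) > 0),
            "cuts must be three increasing values")
  cut(vcrPercent, breaks = c(-Inf, cuts, Inf), right = FALSE,
      labels = c("none", "mild", "moderate", "severe"))
}

#' Measure vertebral compression ratios in a segmented mask
#'
#' Full geometry pipeline: separate instances, locate corner landmarks,
#' compute the compression ratio of every interior vertebra against its two
#' neighbours, and grade it. Heights are reported in the measured frame; when
#' a \linkS4class{GeomTransform} is supplied they are also mapped back to
#' original-image pixels, and to millimetres when pixel spacing is known.
#' The level with the maximum VCR is flagged.
#'
#' @param mask binary matrix, ideally cleaned with [cleanMask()].
#' @param transform optional \linkS4class{GeomTransform} from
#'   [resizeAndPad()].
#' @param anteriorSide \code{"left"} or \code{"right"} (which image edge is
#'   anterior); there is no safe silent default for clinical data, but the
#'   phantom convention is left.
#' @param spacingMm optional length-2 (row, col) pixel spacing in mm of the
#'   original image.
#' @param gradeCuts severity cut points, see [gradeVCR()].
#' @param minArea degenerate-component threshold, see [findCorners()].
#' @return A \linkS4class{VCRReport}.
#' @examples
#' s <- generatePhantom(phantomSpec(compressedIndex = 3,
#'                                  compressionFraction = 0.4))
#' rep <- measureVCR(phantomMask(s))
#' flaggedLevel(rep)
#' @export
measureVCR <- function(mask, transform = NULL,
                       anteriorSide = c("left", "right"), spacingMm = NULL,
                       gradeCuts = c(20, 25, 40), minArea = 12) {
  anteriorSide <- match.arg(anteriorSide)
  sep <- separateInstances(mask)
  n <- length(sep$instances)
  corners <- array(NA_real_, c(4, 2, n),
                   dimnames = list(c("AS", "AI", "PS", "PI"),
                                   c("row", "col"), NULL))
  heights <- numeric(n)
  for (i in seq_len(n)) {
    fc <- findCorners(sep$instances[[i]], anteriorSide, sep$axis, minArea)
    corners[, , i] <- fc$corners
    heights[i] <- fc$anteriorHeight
  }
  instances <- data.frame(
    level = seq_len(n),
    label = vapply(sep$instances, `[[`, integer(1), "label"),
    centroidRow = vapply(sep$instances, function(i) i$centroid[1],
                         numeric(1)),
    centroidCol = vapply(sep$instances, function(i) i$centroid[2],
                         numeric(1)),
    area = vapply(sep$instances, `[[`, integer(1), "area"),
    anteriorHeight = heights)
  if (!is.null(transform)) {
    instances$anteriorHeightOrig <- heights / transform@scale
    if (!is.null(spacingMm))
      instances$anteriorHeightMm <- pixelDistanceMm(heights, transform,
                                                    spacingMm)
  } else if (!is.null(spacingMm)) {
    instances$anteriorHeightMm <- pixelDistanceMm(heights, NULL, spacingMm)
  }
  interior <- seq(2L, n - 1L)
  vcr <- vapply(interior, function(i)
    computeVCR(heights[i - 1], heights[i], heights[i + 1]), numeric(1))
  results <- data.frame(levelIndex = interior,
                        v1 = heights[interior - 1], v2 = heights[interior],
                        v3 = heights[interior + 1], vcrPercent = vcr,
                        grade = gradeVCR(vcr, gradeCuts))
  new("VCRReport", instances = instances, corners = corners,
      results = results, flagged = interior[which.max(vcr)],
      spacingMm = if (is.null(spacingMm)) numeric(0)
                  else as.numeric(spacingMm))
}

#' Write a VCR report to JSON and CSV
#'
#' The CSV has one row per interior level (v1, v2, v3, vcrPercent, grade);
#' the JSON additionally carries the per-vertebra table, corner landmarks
#' and the flagged level.
#'
#' @param report a \linkS4class{VCRReport}.
#' @param stem output path without extension; writes \code{<stem>.json} and
#'   \code{<stem>.csv}.
#' @return Invisibly, the two file paths.
#' @export
writeVCRReport <- function(report, stem) {
  res <- vcrResults(report)
  res$grade <- as.character(res$grade)
  write.csv(res, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(instances = vertebraTable(report), results = res,
         flagged = flaggedLevel(report),
         corners = apply(report@corners, 3, identity, simplify = FALSE)),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(c(paste0(stem, ".json"), paste0(stem, ".csv")))
}
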