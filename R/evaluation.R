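# Pixel-wise validation metrics and agreement statistics.

#' Pixel-wise confusion counts between a predicted and a truth mask
#'
#' @param pred,truth binary matrices of identical shape.
#' @return list with integer fields tp, tn, fp, fn summing to the pixel
#'   total.
#' @export
confusionCounts <- function(pred, truth) {
  stopIfNot(identical(dim(pred), dim(truth)),
            "pred and truth must have identical shapes")
  p <- asBinaryMask(pred); t0 <- asBinaryMask(truth)
  tp <- sum(p == 1L & t0 == 1L)
  tn <- sum(p == 0L & t0 == 0L)
  fp <- sum(p == 1L & t0 == 0L)
  fn <- sum(p == 0L & t0 == 1L)
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Segmentation metrics from confusion counts
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), accuracy
#' (tp+tn)/total, and the dice similarity coefficient
#' 2 tp / (2 tp + fp + fn). Metrics whose denominator is empty (for example
#' sensitivity on an empty truth mask) are reported as \code{NA} rather than
#' silently 0 or 1, so they drop out of summaries visibly.
#'
#' @param counts list with tp, tn, fp, fn (see [confusionCounts()]).
#' @return named numeric vector (sensitivity, specificity, accuracy, dsc).
#' @examples
#' segMetrics(list(tp = 2, tn = 11, fp = 1, fn = 1))
#' @export
segMetrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  stopIfNot(all(c(tp, tn, fp, fn) >= 0), "counts must be non-negative")
  total <- tp + tn + fp + fn
  stopIfNot(total > 0, "all-zero confusion counts")
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  c(sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    accuracy = (tp + tn) / total,
    dsc = safe(2 * tp, 2 * tp + fp + fn))
}

#' Per-image segmentation metrics with mean and standard deviation
#'
#' Computes [segMetrics()] for each prediction/truth pair and summarises
#' with the mean and (n-1) standard deviation across images; undefined
#' per-image values are excluded from the summary.
#'
#' @param preds,truths paired lists of binary matrices.
#' @return list with \code{perImage} (data.frame), \code{mean} and \code{sd}
#'   (named numeric vectors).
#' @export
segMetricsSet <- function(preds, truths) {
  stopIfNot(length(preds) == length(truths) && length(preds) >= 1,
            "preds and truths must be non-empty paired lists")
  rows <- t(vapply(seq_along(preds), function(i)
    segMetrics(confusionCounts(preds[[i]], truths[[i]])), numeric(4)))
  perImage <- as.data.frame(rows)
  list(perImage = perImage,
       mean = vapply(perImage, mean, numeric(1), na.rm = TRUE),
       sd = vapply(perImage, sd, numeric(1), na.rm = TRUE))
}

#' ROC and precision-recall curves over pooled pixels
#'
#' Pixels from all probability maps are pooled; curve points are computed at
#' every distinct threshold (descending, ties grouped) and both areas use
#' the trapezoidal rule. With ties grouped this ROC area equals the
#' normalised Mann-Whitney U statistic. ROC requires both classes present.
#'
#' @param probMaps list of probability matrices (values in [0, 1]), or one
#'   matrix/vector.
#' @param truths list of matching binary matrices, or one matrix/vector.
#' @return list with \code{roc} (data.frame threshold/fpr/tpr, plus
#'   \code{auc}) and \code{pr} (data.frame threshold/recall/precision, plus
#'   \code{auc}).
#' @examples
#' truth <- c(0, 0, 1, 1)
#' rocPrCurves(c(.1, .4, .35, .8), truth)$roc$auc
#' @export
rocPrCurves <- function(probMaps, truths) {
  if (!is.list(probMaps)) probMaps <- list(probMaps)
  if (!is.list(truths)) truths <- list(truths)
  p <- unlist(lapply(probMaps, as.numeric))
  y <- unlist(lapply(truths, function(m) as.integer(as.numeric(m) != 0)))
  stopIfNot(length(p) == length(y), "probabilities and truths differ in size")
  stopIfNot(min(p) >= 0 && max(p) <= 1, "probabilities must be in [0, 1]")
  nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
  stopIfNot(nPos > 0 && nNeg > 0,
            "ROC undefined: truth contains a single class %s",
            "(no positives or no negatives)")
  ord <- order(p, decreasing = TRUE)
  ps <- p[ord]; ys <- y[ord]
  # group tied thresholds: cumulative counts at the last index of each group
  last <- which(diff(ps) != 0)
  idx <- c(last, length(ps))
  cumPos <- cumsum(ys)[idx]
  cumNeg <- idx - cumPos
  thr <- ps[idx]
  tpr <- c(0, cumPos / nPos)
  fpr <- c(0, cumNeg / nNeg)
  rocAuc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  recall <- cumPos / nPos
  precision <- cumPos / (cumPos + cumNeg)
  # PR curve: prepend the (recall -> 0) anchor at the first point's precision
  rec <- c(0, recall)
  prec <- c(precision[1], precision)
  prAuc <- sum(diff(rec) * (head(prec, -1) + prec[-1]) / 2)
  list(roc = list(curve = data.frame(threshold = c(Inf, thr),
                                     fpr = fpr, tpr = tpr),
                  auc = rocAuc),
       pr = list(curve = data.frame(threshold = thr, recall = recall,
                                    precision = precision),
                 auc = prAuc))
}

#' Plot ROC and precision-recall curves
#'
#' Base-graphics rendering of the two curves from [rocPrCurves()], side by
#' side, with the areas in the panel titles.
#'
#' @param curves result of [rocPrCurves()].
#' @return Invisibly, \code{curves}.
#' @export
plotCurves <- function(curves) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(curves$roc$curve$fpr, curves$roc$curve$tpr, type = "l",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (AUC %.3f)", curves$roc$auc))
  graphics::abline(0, 1, lty = 3)
  plot(curves$pr$curve$recall, curves$pr$curve$precision, type = "l",
       xlab = "recall", ylab = "precision", ylim = c(0, 1),
       main = sprintf("PR (AUC %.3f)", curves$pr$auc))
  invisible(curves)
}

#' Bland-Altman plot of two VCR series
#'
#' Differences against means with the bias and the 1.96-sd limits of
#' agreement drawn as horizontal lines.
#'
#' @param a,b paired numeric series (see [agreementStats()]).
#' @return Invisibly, the [agreementStats()] of the pair.
#' @export
plotBlandAltman <- function(a, b) {
  ag <- agreementStats(a, b)
  plot((a + b) / 2, a - b, xlab = "mean of methods",
       ylab = "difference (a - b)",
       main = sprintf("Bland-Altman (bias %.2f)", ag$bias))
  graphics::abline(h = c(ag$loaLow, ag$bias, ag$loaHigh),
                   lty = c(2, 1, 2))
  invisible(ag)
}

#' Agreement between two compression-ratio series
#'
#' Pearson correlation plus Bland-Altman statistics of the paired
#' differences a - b: the bias (mean difference) and the limits of agreement
#' at bias +/- 1.96 times the sample (n-1) standard deviation, with the
#' fraction of pairs falling inside the limits. Series with zero variance
#' have an undefined correlation, reported as \code{NA} with a warning.
#'
#' @param a,b equal-length numeric vectors (n >= 3) of paired measurements.
#' @return list with r, bias, loaLow, loaHigh, sdDiff, fractionWithin, n.
#' @examples
#' agreementStats(c(10, 20, 30), c(12, 18, 30))
#' @export
agreementStats <- function(a, b) {
  stopIfNot(length(a) == length(b), "series must be paired")
  stopIfNot(length(a) >= 3, "need at least 3 pairs, got %d", length(a))
  stopIfNot(all(is.finite(a)) && all(is.finite(b)),
            "series must be finite")
  r <- if (sd(a) == 0 || sd(b) == 0) {
    warning("zero variance in a series: correlation undefined")
    NA_real_
  } else cor(a, b)
  d <- a - b
  bias <- mean(d)
  sdd <- sd(d)
  lo <- bias - 1.96 * sdd
  hi <- bias + 1.96 * sdd
  list(r = r, bias = bias, loaLow = lo, loaHigh = hi, sdDiff = sdd,
       fractionWithin = mean(d >= lo & d <= hi), n = length(a))
}
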