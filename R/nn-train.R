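#' Training configuration
#'
#' Optimisation settings for dice-loss training with Adam: learning rate
#' 0.001, batch size 10, 200 epochs, and a reduce-on-plateau learning-rate
#' schedule monitoring the validation loss (factor 0.1, patience 10,
#' floor 1e-6). The dice smoothing constant defaults to 1 so empty masks
#' never produce 0/0; set \code{smooth = 0} for the exact hard-count form.
#'
#' @param learningRate initial Adam learning rate, default 0.001.
#' @param batchSize minibatch size, default 10.
#' @param epochs training epochs, default 200.
#' @param scheduleFactor,schedulePatience,scheduleMinLr reduce-on-plateau
#'   parameters: multiply the learning rate by \code{scheduleFactor} after
#'   \code{schedulePatience} epochs without validation-loss improvement,
#'   never below \code{scheduleMinLr}.
#' @param beta1,beta2,epsilon Adam moment parameters, defaults
#'   (0.9, 0.999, 1e-7).
#' @param smooth dice smoothing constant, default 1.
#' @param seed master seed controlling shuffling (and fold assignment in
#'   [crossValidate()]).
#' @param folds folds for cross-validation, default 5.
#' @return A validated list of class \code{"TrainConfig"}.
#' @export
trainConfig <- function(learningRate = 0.001, batchSize = 10L, epochs = 200L,
                        scheduleFactor = 0.1, schedulePatience = 10L,
                        scheduleMinLr = 1e-6, beta1 = 0.9, beta2 = 0.999,
                        epsilon = 1e-7, smooth = 1, seed = 1L, folds = 5L) {
  stopIfNot(learningRate > 0, "learningRate must be > 0")
  stopIfNot(batchSize >= 1, "batchSize must be >= 1")
  stopIfNot(epochs >= 1, "epochs must be >= 1")
  stopIfNot(folds >= 2, "folds must be >= 2 for cross-validation")
  stopIfNot(smooth >= 0, "smooth must be >= 0")
  cfg <- list(learningRate = learningRate, batchSize = as.integer(batchSize),
              epochs = as.integer(epochs), scheduleFactor = scheduleFactor,
              schedulePatience = as.integer(schedulePatience),
              scheduleMinLr = scheduleMinLr, beta1 = beta1, beta2 = beta2,
              epsilon = epsilon, smooth = smooth, seed = as.integer(seed),
              folds = as.integer(folds))
  class(cfg) <- "TrainConfig"
  cfg
}

#' Soft dice loss
#'
#' \code{1 - (2 TP + s) / (2 TP + FP + FN + s)} with soft confusion counts
#' \code{TP = sum(pred * truth)}, \code{FP = sum(pred * (1 - truth))},
#' \code{FN = sum((1 - pred) * truth)}. For binary predictions with
#' \code{smooth = 0} this is exactly one minus the dice similarity
#' coefficient.
#'
#' @param pred numeric array of probabilities in [0, 1].
#' @param truth binary array of the same shape.
#' @param smooth smoothing constant >= 0, default 1.
#' @return scalar loss in [0, 1].
#' @examples
#' diceLoss(c(1, 1, 0, 1), c(1, 1, 1, 0), smooth = 0)  # 1 - 4/6
#' @export
diceLoss <- function(pred, truth, smooth = 1) {
  stopIfNot(length(pred) == length(truth) &&
            identical(dim(pred) %||% length(pred),
                      dim(truth) %||% length(truth)),
            "pred and truth must have identical shapes")
  stopIfNot(min(pred) >= 0 && max(pred) <= 1, "pred must be in [0, 1]")
  tp <- sum(pred * truth)
  denom <- sum(pred) + sum(truth) + smooth   # = 2TP + FP + FN + smooth
  stopIfNot(denom > 0, "dice loss undefined: both masks empty and smooth 0")
  1 - (2 * tp + smooth) / denom
}

# gradient of the soft dice loss w.r.t. pred
diceLossGrad <- function(pred, truth, smooth = 1) {
  num <- 2 * sum(pred * truth) + smooth
  den <- sum(pred) + sum(truth) + smooth
  -(2 * truth * den - num) / den^2
}

#' Reduce-on-plateau learning-rate trace
#'
#' Pure replay of the schedule used during training: starting from
#' \code{lr0}, the learning rate is multiplied by \code{factor} once the
#' monitored loss has failed to improve for \code{patience} consecutive
#' epochs, never dropping below \code{minLr}. Returns the learning rate in
#' effect at each epoch (after any reduction triggered by that epoch's
#' monitored value).
#'
#' @param monitored numeric vector of per-epoch monitored losses.
#' @param lr0 initial learning rate.
#' @param factor,patience,minLr schedule parameters.
#' @return numeric vector of learning rates, same length as
#'   \code{monitored}.
#' @examples
#' plateauTrace(c(1, 1, 1), lr0 = 1e-3, factor = 0.1, patience = 2)
#' @export
plateauTrace <- function(monitored, lr0, factor = 0.1, patience = 10L,
                         minLr = 1e-6) {
  lr <- lr0
  best <- Inf
  wait <- 0L
  out <- numeric(length(monitored))
  for (i in seq_along(monitored)) {
    if (monitored[i] < best) {
      best <- monitored[i]
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) {
        lr <- max(lr * factor, minLr)
        wait <- 0L
      }
    }
    out[i] <- lr
  }
  out
}

# one Adam update over every layer parameter; clears gradients
adamStep <- function(model, lr, cfg) {
  net <- model@net
  net$adamT <- net$adamT + 1L
  t <- net$adamT
  c1 <- 1 - cfg$beta1^t
  c2 <- 1 - cfg$beta2^t
  for (l in net$layers) {
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      l$m[[nm]] <- cfg$beta1 * l$m[[nm]] + (1 - cfg$beta1) * g
      l$v[[nm]] <- cfg$beta2 * l$v[[nm]] + (1 - cfg$beta2) * g * g
      l$params[[nm]] <- l$params[[nm]] -
        lr * (l$m[[nm]] / c1) / (sqrt(l$v[[nm]] / c2) + cfg$epsilon)
      l$grads[[nm]][] <- 0
    }
  }
  invisible(NULL)
}

# stack a list of H x W matrices (indices idx) into a (H,W,1,n) batch
asBatch <- function(mats, idx) {
  d <- dim(mats[[idx[1]]])
  x <- array(0, c(d[1], d[2], 1L, length(idx)))
  for (j in seq_along(idx)) x[, , 1L, j] <- mats[[idx[j]]]
  x
}

batchLoss <- function(model, images, masks, idx, batchSize, smooth) {
  total <- 0
  n <- 0
  for (start in seq(1, length(idx), by = batchSize)) {
    take <- idx[start:min(start + batchSize - 1, length(idx))]
    p <- modelForward(model, asBatch(images, take), training = FALSE)$p
    total <- total + diceLoss(p, asBatch(masks, take), smooth) * length(take)
    n <- n + length(take)
  }
  total / n
}

#' Train the model with dice loss and Adam
#'
#' Minimises the soft dice loss over minibatches with Adam; the learning
#' rate follows the reduce-on-plateau schedule on the validation loss. The
#' weights achieving the best validation loss are restored at the end. Fully
#' reproducible for a fixed config seed (shuffling) and model seed
#' (initialisation).
#'
#' @param model an \linkS4class{MDR2UNet} from [buildModel()].
#' @param trainImages,trainMasks lists of matrices at the model input size;
#'   images in [0, 1], masks binary.
#' @param valImages,valMasks validation set in the same form.
#' @param cfg a [trainConfig()].
#' @param verbose print per-epoch losses.
#' @return list with \code{model} (trained, best-validation weights),
#'   \code{history} (data.frame epoch / trainLoss / valLoss / lr) and
#'   \code{bestEpoch}.
#' @export
trainModel <- function(model, trainImages, trainMasks, valImages, valMasks,
                       cfg = trainConfig(), verbose = FALSE) {
  stopIfNot(length(trainImages) >= 1 && length(valImages) >= 1,
            "training and validation sets must be non-empty")
  stopIfNot(length(trainImages) == length(trainMasks) &&
            length(valImages) == length(valMasks),
            "images and masks must be paired")
  insz <- model@config$inputSize
  for (im in c(trainImages, valImages))
    stopIfNot(all(dim(im) == insz),
              "all images must be preprocessed to %d x %d",
              insz[1], insz[2])
  n <- length(trainImages)
  lr <- cfg$learningRate
  best <- Inf
  bestEpoch <- 0L
  bestWeights <- NULL
  wait <- 0L
  hist <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                     valLoss = numeric(0), lr = numeric(0))
  for (epoch in seq_len(cfg$epochs)) {
    ord <- withSeed(childSeed(cfg$seed, epoch), sample.int(n))
    epochLoss <- 0
    for (start in seq(1, n, by = cfg$batchSize)) {
      take <- ord[start:min(start + cfg$batchSize - 1, n)]
      x <- asBatch(trainImages, take)
      truth <- asBatch(trainMasks, take)
      fw <- modelForward(model, x, training = TRUE)
      loss <- diceLoss(fw$p, truth, cfg$smooth)
      stopIfNot(is.finite(loss),
                "non-finite training loss at epoch %d; %s", epoch,
                "check input scaling and learning rate")
      modelBackward(model, fw$cache, diceLossGrad(fw$p, truth, cfg$smooth))
      adamStep(model, lr, cfg)
      epochLoss <- epochLoss + loss * length(take)
    }
    valLoss <- batchLoss(model, valImages, valMasks, seq_along(valImages),
                         cfg$batchSize, cfg$smooth)
    # reduce-on-plateau on the validation loss
    if (valLoss < best) {
      best <- valLoss
      bestEpoch <- epoch
      bestWeights <- modelWeights(model)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$schedulePatience) {
        lr <- max(lr * cfg$scheduleFactor, cfg$scheduleMinLr)
        wait <- 0L
      }
    }
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   trainLoss = epochLoss / n,
                                   valLoss = valLoss, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2g",
                      epoch, epochLoss / n, valLoss, lr))
  }
  if (!is.null(bestWeights)) setModelWeights(model, bestWeights)
  list(model = model, history = hist, bestEpoch = bestEpoch)
}

#' Seeded k-fold cross-validation
#'
#' Assigns every sample to exactly one validation fold (deterministic for a
#' fixed seed), trains a freshly initialised model per fold and reports
#' per-fold pixel metrics of the thresholded predictions on the held-out
#' fold, plus their mean and standard deviation.
#'
#' @param images,masks paired lists of matrices (images in [0, 1], masks
#'   binary) at the model input size.
#' @param cfg a [trainConfig()]; \code{cfg$folds} folds are used.
#' @param modelCfg a [modelConfig()].
#' @param threshold probability cut for the predicted masks.
#' @return list with \code{folds} (assignment vector), \code{perFold}
#'   (data.frame of per-fold mean metrics) and \code{summary} (mean and sd
#'   across folds).
#' @export
crossValidate <- function(images, masks, cfg, modelCfg, threshold = 0.5) {
  n <- length(images)
  stopIfNot(cfg$folds <= n,
            "cannot split %d samples into %d folds", n, cfg$folds)
  assign <- withSeed(cfg$seed, sample(rep_len(seq_len(cfg$folds), n)))
  perFold <- NULL
  for (f in seq_len(cfg$folds)) {
    trIdx <- which(assign != f)
    vaIdx <- which(assign == f)
    model <- buildModel(modelCfg, seed = childSeed(cfg$seed, f))
    fit <- trainModel(model, images[trIdx], masks[trIdx],
                      images[vaIdx], masks[vaIdx], cfg)
    preds <- lapply(vaIdx, function(i)
      predictMask(fit$model, images[[i]], threshold)$mask)
    ms <- segMetricsSet(preds, masks[vaIdx])
    perFold <- rbind(perFold,
                     cbind(data.frame(fold = f), as.data.frame(
                       t(ms$mean))))
  }
  metricCols <- setdiff(names(perFold), "fold")
  list(folds = assign, perFold = perFold,
       summary = data.frame(metric = metricCols,
                            mean = vapply(perFold[metricCols], mean,
                                          numeric(1)),
                            sd = vapply(perFold[metricCols], sd,
                                        numeric(1))))
}
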