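# MDR2-UNet: block definitions and the U-shaped graph.
#
# Encoder stage 1 is a multi-dilated residual block (MDRB): parallel dilated
# convolutions (one per configured rate, each conv -> BN -> ReLU), channel
# concatenation (width multiplies by the number of rates), a 1x1 bottleneck
# back to the configured width, and a shortcut from the block input added
# before the final ReLU. All remaining stages, the bridge and the decoder
# are recurrent residual blocks (RRB): a 1x1 input projection, a
# weight-shared 3x3 convolution applied recurrenceSteps times with the
# projection re-added at every step (feature accumulation), wrapped in a
# residual shortcut. Skip connections concatenate each encoder stage's
# pre-pooling feature map into the decoder; a final 1x1 convolution with a
# sigmoid gives the per-pixel foreground probability.

#' Model configuration for the MDR2-UNet
#'
#' @param depth number of resolution levels (>= 2), default 5.
#' @param baseFilters channels at level 1, default 64 (use 8-16 for
#'   desk-scale experiments).
#' @param dilationRates strictly increasing dilation rates of the MDRB
#'   branches, default \code{c(2, 4, 8, 16)}.
#' @param recurrenceSteps steps of the weight-shared recurrent convolution,
#'   default 2.
#' @param inputSize length-2 (rows, cols); each side must be divisible by
#'   \code{2^(depth - 1)}. Default \code{c(512, 512)}.
#' @param kernelSize odd convolution kernel size, default 3.
#' @param mdrbStages encoder stages built as MDRB (default 1, the first;
#'   more may be listed for experimentation).
#' @return A validated list of class \code{"ModelConfig"}.
#' @examples
#' cfg <- modelConfig(depth = 4, baseFilters = 8, inputSize = c(128, 128))
#' @export
modelConfig <- function(depth = 5L, baseFilters = 64L,
                        dilationRates = c(2L, 4L, 8L, 16L),
                        recurrenceSteps = 2L, inputSize = c(512L, 512L),
                        kernelSize = 3L, mdrbStages = 1L) {
  stopIfNot(depth >= 2, "depth must be >= 2, got %d", depth)
  stopIfNot(length(dilationRates) >= 1 && all(dilationRates >= 1) &&
            all(diff(dilationRates) > 0),
            "dilationRates must be non-empty, strictly increasing, all >= 1")
  stopIfNot(recurrenceSteps >= 1, "recurrenceSteps must be >= 1, got %d",
            recurrenceSteps)
  stopIfNot(kernelSize %% 2 == 1 && kernelSize >= 1,
            "kernelSize must be odd and >= 1")
  div <- 2^(depth - 1)
  stopIfNot(all(inputSize %% div == 0),
            "input size %d x %d not divisible by 2^(depth-1) = %d",
            inputSize[1], inputSize[2], div)
  cfg <- list(depth = as.integer(depth),
              baseFilters = as.integer(baseFilters),
              dilationRates = as.integer(dilationRates),
              recurrenceSteps = as.integer(recurrenceSteps),
              inputSize = as.integer(inputSize),
              kernelSize = as.integer(kernelSize),
              mdrbStages = as.integer(mdrbStages))
  class(cfg) <- "ModelConfig"
  cfg
}

#' Effective kernel size of a dilated convolution
#'
#' A k-tap kernel at dilation rate r spans
#' \code{k + (k - 1) * (r - 1)} input pixels per axis: the zero insertions
#' inside the filter enlarge the receptive field without adding weights.
#'
#' @param kernelSize odd kernel size >= 1.
#' @param rate dilation rate >= 1.
#' @return integer effective extent.
#' @examples
#' effectiveKernel(3, 16)  # 33
#' @export
effectiveKernel <- function(kernelSize, rate) {
  stopIfNot(kernelSize >= 1 && kernelSize %% 2 == 1,
            "kernelSize must be odd and >= 1")
  stopIfNot(rate >= 1, "rate must be >= 1")
  as.integer(kernelSize + (kernelSize - 1) * (rate - 1))
}

# ---- blocks ----------------------------------------------------------------

buildMDRB <- function(cin, cout, cfg) {
  rates <- cfg$dilationRates
  b <- new.env(parent = emptyenv())
  b$kind <- "MDRB"
  b$cin <- cin; b$cout <- cout; b$rates <- rates
  b$branchConv <- lapply(rates, function(r)
    newConv(cfg$kernelSize, cin, cout, dilation = r))
  b$branchBN <- lapply(rates, function(r) newBN(cout))
  b$bottleneck <- newConv(1L, cout * length(rates), cout)
  b$bnOut <- newBN(cout)
  b$proj <- if (cin != cout) newConv(1L, cin, cout) else NULL
  b
}

mdrbFw <- function(b, x, training) {
  nb <- length(b$rates)
  caches <- vector("list", nb)
  concat <- NULL
  for (i in seq_len(nb)) {
    c1 <- convFw(b$branchConv[[i]], x)
    n1 <- bnFw(b$branchBN[[i]], c1$y, training)
    a1 <- reluFw(n1$y)
    caches[[i]] <- list(conv = c1$cache, bn = n1$cache, relu = a1$cache)
    concat <- if (is.null(concat)) a1$y else catChannels(concat, a1$y)
  }
  bt <- convFw(b$bottleneck, concat)
  nb2 <- bnFw(b$bnOut, bt$y, training)
  if (is.null(b$proj)) {
    sc <- x; scCache <- NULL
  } else {
    p <- convFw(b$proj, x); sc <- p$y; scCache <- p$cache
  }
  a <- reluFw(nb2$y + sc)
  list(y = a$y,
       cache = list(branches = caches, bottleneck = bt$cache,
                    bnOut = nb2$cache, relu = a$cache, scCache = scCache))
}

mdrbBw <- function(b, cache, dy) {
  dz <- reluBw(cache$relu, dy)
  dsc <- dz                               # shortcut path
  dbn <- bnBw(b$bnOut, cache$bnOut, dz)
  dconcat <- convBw(b$bottleneck, cache$bottleneck, dbn)
  nb <- length(b$rates)
  dx <- if (is.null(b$proj)) dsc
        else convBw(b$proj, cache$scCache, dsc)
  for (i in seq_len(nb)) {
    di <- dconcat[, , (i - 1) * b$cout + seq_len(b$cout), , drop = FALSE]
    da <- reluBw(cache$branches[[i]]$relu, di)
    dn <- bnBw(b$branchBN[[i]], cache$branches[[i]]$bn, da)
    dx <- dx + convBw(b$branchConv[[i]], cache$branches[[i]]$conv, dn)
  }
  dx
}

buildRRB <- function(cin, cout, cfg) {
  b <- new.env(parent = emptyenv())
  b$kind <- "RRB"
  b$cin <- cin; b$cout <- cout
  b$steps <- cfg$recurrenceSteps
  b$proj <- newConv(1L, cin, cout)
  b$conv <- newConv(cfg$kernelSize, cout, cout)
  b$bn <- newBN(cout)
  b
}

rrbFw <- function(b, x, training) {
  pr <- convFw(b$proj, x)
  p <- pr$y
  h <- p
  steps <- vector("list", b$steps)
  for (s in seq_len(b$steps)) {
    c1 <- convFw(b$conv, h)
    n1 <- bnFw(b$bn, c1$y + p, training)
    a1 <- reluFw(n1$y)
    steps[[s]] <- list(conv = c1$cache, bn = n1$cache, relu = a1$cache)
    h <- a1$y
  }
  list(y = h + p, cache = list(proj = pr$cache, steps = steps))
}

rrbBw <- function(b, cache, dy) {
  dh <- dy
  dp <- dy                                # residual shortcut
  for (s in rev(seq_len(b$steps))) {
    da <- reluBw(cache$steps[[s]]$relu, dh)
    dz <- bnBw(b$bn, cache$steps[[s]]$bn, da)
    dp <- dp + dz                         # p re-added at every step
    dh <- convBw(b$conv, cache$steps[[s]]$conv, dz)
  }
  dp <- dp + dh                           # h0 = p feeds the first step
  convBw(b$proj, cache$proj, dp)
}

blockFw <- function(b, x, training) {
  if (b$kind == "MDRB") mdrbFw(b, x, training) else rrbFw(b, x, training)
}
blockBw <- function(b, cache, dy) {
  if (b$kind == "MDRB") mdrbBw(b, cache, dy) else rrbBw(b, cache, dy)
}

blockLayers <- function(b) {
  if (b$kind == "MDRB")
    c(b$branchConv, b$branchBN, list(b$bottleneck, b$bnOut),
      if (!is.null(b$proj)) list(b$proj))
  else list(b$proj, b$conv, b$bn)
}

# ---- the model -------------------------------------------------------------

#' Build an MDR2-UNet
#'
#' Constructs the full encoder-decoder from a [modelConfig()]: encoder
#' stage 1 is an MDRB (more stages via \code{mdrbStages}), every other stage
#' and the decoder are RRBs; channels double per level down and halve per
#' level up; skips concatenate pre-pooling feature maps; upsampling is a
#' learned 2x2 transposed convolution; the head is a 1x1 convolution with
#' sigmoid. Weight initialisation is He-normal with zero biases, drawn from
#' a seeded RNG so construction is reproducible.
#'
#' @param cfg a [modelConfig()].
#' @param seed integer seed for weight initialisation.
#' @return An \linkS4class{MDR2UNet}.
#' @examples
#' m <- buildModel(modelConfig(depth = 3, baseFilters = 4,
#'                             inputSize = c(32, 32)))
#' modelParameterCount(m)
#' @export
buildModel <- function(cfg, seed = 1L) {
  stopIfNot(inherits(cfg, "ModelConfig"), "cfg must come from modelConfig()")
  net <- new.env(parent = emptyenv())
  withSeed(seed, {
    depth <- cfg$depth
    ch <- cfg$baseFilters * 2^(seq_len(depth) - 1)
    net$enc <- vector("list", depth)
    for (l in seq_len(depth)) {
      cin <- if (l == 1) 1L else ch[l - 1]
      net$enc[[l]] <- if (l %in% cfg$mdrbStages)
        buildMDRB(cin, ch[l], cfg) else buildRRB(cin, ch[l], cfg)
    }
    net$up <- vector("list", depth - 1)
    net$dec <- vector("list", depth - 1)
    for (l in seq_len(depth - 1)) {
      net$up[[l]] <- newConvT(ch[l + 1], ch[l])
      net$dec[[l]] <- buildRRB(2L * ch[l], ch[l], cfg)
    }
    net$head <- newConv(1L, ch[1], 1L)
  })
  net$layers <- c(unlist(lapply(net$enc, blockLayers), recursive = FALSE),
                  net$up,
                  unlist(lapply(net$dec, blockLayers), recursive = FALSE),
                  list(net$head))
  net$adamT <- 0L
  new("MDR2UNet", config = unclass(cfg), net = net)
}

# forward pass over a (H,W,1,N) batch; returns probabilities and, when
# backprop = TRUE, the caches needed for modelBackward()
modelForward <- function(model, x, training = FALSE, backprop = training) {
  net <- model@net
  depth <- model@config$depth
  enc <- vector("list", depth)
  pools <- vector("list", depth - 1)
  s <- x
  for (l in seq_len(depth)) {
    enc[[l]] <- blockFw(net$enc[[l]], s, training)
    if (l < depth) {
      pools[[l]] <- poolFw(enc[[l]]$y)
      s <- pools[[l]]$y
    }
  }
  d <- enc[[depth]]$y
  ups <- vector("list", depth - 1)
  dec <- vector("list", depth - 1)
  for (l in rev(seq_len(depth - 1))) {
    ups[[l]] <- convTFw(net$up[[l]], d)
    cat1 <- catChannels(enc[[l]]$y, ups[[l]]$y)
    dec[[l]] <- blockFw(net$dec[[l]], cat1, training)
    d <- dec[[l]]$y
  }
  hd <- convFw(net$head, d)
  p <- sigmoidFw(hd$y)
  cache <- if (backprop)
    list(enc = enc, pools = pools, ups = ups, dec = dec, head = hd$cache,
         p = p)
  list(p = p, cache = cache)
}

# backward pass from dL/dprob; accumulates parameter gradients in the net
modelBackward <- function(model, cache, dp) {
  net <- model@net
  depth <- model@config$depth
  dlogit <- dp * cache$p * (1 - cache$p)
  d <- convBw(net$head, cache$head, dlogit)
  dskip <- vector("list", depth)
  for (l in seq_len(depth - 1)) {
    dcat <- blockBw(net$dec[[l]], cache$dec[[l]]$cache, d)
    cskip <- net$enc[[l]]$cout
    sp <- splitChannels(dcat, cskip)
    dskip[[l]] <- sp$a
    d <- convTBw(net$up[[l]], cache$ups[[l]]$cache, sp$b)
  }
  # d now carries the gradient flowing into the bridge (deepest encoder)
  for (l in rev(seq_len(depth))) {
    dy <- if (l == depth) d else
      poolBw(cache$pools[[l]]$cache, d) + dskip[[l]]
    d <- blockBw(net$enc[[l]], cache$enc[[l]]$cache, dy)
  }
  invisible(NULL)
}

#' Total number of trainable parameters
#'
#' Batch-normalisation scale/shift parameters are counted; running statistics
#' are not. The recurrent convolution shares its weights across steps, so the
#' count is independent of \code{recurrenceSteps}.
#'
#' @param model an \linkS4class{MDR2UNet}.
#' @return integer parameter count.
#' @export
modelParameterCount <- function(model) {
  sum(vapply(model@net$layers, layerParamCount, integer(1)))
}

#' Segment one preprocessed image
#'
#' Runs the forward pass in inference mode and thresholds the probability
#' map. The image must already be at the model's input size (run
#' [preprocessRadiograph()] first) with values in [0, 1].
#'
#' @param model an \linkS4class{MDR2UNet}.
#' @param image numeric matrix at the model input size, values in [0, 1].
#' @param threshold probability cut in (0, 1), default 0.5.
#' @return list with \code{prob} (matrix of probabilities) and \code{mask}
#'   (0/1 integer matrix, \code{prob >= threshold}).
#' @export
predictMask <- function(model, image, threshold = 0.5) {
  cfg <- model@config
  stopIfNot(threshold > 0 && threshold < 1, "threshold must be in (0, 1)")
  stopIfNot(is.matrix(image), "image must be a matrix")
  stopIfNot(all(dim(image) == cfg$inputSize),
            "image is %d x %d but the model expects %d x %d: %s",
            nrow(image), ncol(image), cfg$inputSize[1], cfg$inputSize[2],
            "run preprocessRadiograph() first")
  stopIfNot(max(image) <= 1 + 1e-9 && min(image) >= 0,
            "image values must be scaled to [0, 1]")
  x <- array(image, c(dim(image), 1L, 1L))
  p <- modelForward(model, x, training = FALSE)$p
  prob <- matrix(p, nrow(image), ncol(image))
  list(prob = prob, mask = matrix(as.integer(prob >= threshold),
                                  nrow(image), ncol(image)))
}

#' Extract / restore model weights
#'
#' \code{modelWeights} returns a plain named list of numeric arrays (one per
#' layer parameter) that fully determines the trained model together with
#' its config; \code{setModelWeights} writes such a list back. Together with
#' [modelConfig()] this gives a lossless serialisation round trip.
#'
#' @param model an \linkS4class{MDR2UNet}.
#' @return named list of arrays.
#' @export
modelWeights <- function(model) {
  lapply(model@net$layers, function(l)
    c(l$params, if (l$type == "bn")
        list(runMean = l$runMean, runVar = l$runVar)))
}

#' @rdname modelWeights
#' @param weights a list previously produced by \code{modelWeights}.
#' @export
setModelWeights <- function(model, weights) {
  layers <- model@net$layers
  stopIfNot(length(weights) == length(layers),
            "weight list length %d does not match the model's %d layers",
            length(weights), length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (nm in names(l$params)) {
      stopIfNot(length(weights[[i]][[nm]]) == length(l$params[[nm]]),
                "shape mismatch in layer %d parameter %s", i, nm)
      l$params[[nm]][] <- weights[[i]][[nm]]
    }
    if (l$type == "bn") {
      l$runMean[] <- weights[[i]]$runMean
      l$runVar[] <- weights[[i]]$runVar
    }
  }
  invisible(model)
}

#' Save / load a trained model
#'
#' The checkpoint is an RDS file holding the config and the weight list; a
#' side-car JSON of the config is written next to it for inspection.
#'
#' @param model an \linkS4class{MDR2UNet}.
#' @param path checkpoint file path (\code{.rds}).
#' @return \code{loadModel} returns the restored \linkS4class{MDR2UNet}.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(config = model@config, weights = modelWeights(model)), path)
  jsonlite::write_json(model@config, paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  cfg <- do.call(modelConfig, obj$config[c("depth", "baseFilters",
                                           "dilationRates",
                                           "recurrenceSteps", "inputSize",
                                           "kernelSize", "mdrbStages")])
  model <- buildModel(cfg, seed = 0L)
  setModelWeights(model, obj$weights)
  model
}
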