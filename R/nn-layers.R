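# Primitive differentiable layers for the segmentation network.
#
# Tensors are R arrays dim (H, W, C, N), column-major. Each layer is an
# environment holding its parameters ($params), accumulated gradients
# ($grads) and Adam moments ($m, $v). Forward functions return
# list(y, cache); backward functions take (layer, cache, dy), accumulate
# into $grads and return dx. All heavy kernels live in src/kernels.cpp.

newLayer <- function(type, params) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- params
  e$grads <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  e$m <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  e$v <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# He-normal initialisation for ReLU networks; draws from the current RNG
# stream so model construction is reproducible under withSeed().
newConv <- function(k, cin, cout, dilation = 1L) {
  sdv <- sqrt(2 / (k * k * cin))
  W <- array(rnorm(k * k * cin * cout, sd = sdv), c(k, k, cin, cout))
  l <- newLayer("conv", list(W = W, b = numeric(cout)))
  l$dilation <- as.integer(dilation)
  l
}

convFw <- function(layer, x) {
  y <- .conv2dForward(x, layer$params$W, layer$params$b, layer$dilation)
  list(y = y, cache = x)
}

convBw <- function(layer, cache, dy) {
  g <- .conv2dBackward(cache, layer$params$W, dy, layer$dilation)
  layer$grads$W <- layer$grads$W + g$dw
  layer$grads$b <- layer$grads$b + g$db
  g$dx
}

newConvT <- function(cin, cout) {
  sdv <- sqrt(2 / (4 * cin))
  W <- array(rnorm(4 * cin * cout, sd = sdv), c(2, 2, cin, cout))
  newLayer("convT", list(W = W, b = numeric(cout)))
}

convTFw <- function(layer, x) {
  list(y = .convT2Forward(x, layer$params$W, layer$params$b), cache = x)
}

convTBw <- function(layer, cache, dy) {
  g <- .convT2Backward(cache, layer$params$W, dy)
  layer$grads$W <- layer$grads$W + g$dw
  layer$grads$b <- layer$grads$b + g$db
  g$dx
}

newBN <- function(c, momentum = 0.9, eps = 1e-5) {
  l <- newLayer("bn", list(gamma = rep(1, c), beta = numeric(c)))
  l$runMean <- numeric(c)
  l$runVar <- rep(1, c)
  l$momentum <- momentum
  l$eps <- eps
  l
}

bnFw <- function(layer, x, training) {
  if (training) {
    r <- .bnTrainForward(x, layer$params$gamma, layer$params$beta,
                         layer$eps)
    mom <- layer$momentum
    va <- 1 / r$invstd^2 - layer$eps
    layer$runMean <- mom * layer$runMean + (1 - mom) * r$mu
    layer$runVar <- mom * layer$runVar + (1 - mom) * va
    list(y = r$y, cache = list(x = x, mu = r$mu, invstd = r$invstd))
  } else {
    scale <- layer$params$gamma / sqrt(layer$runVar + layer$eps)
    shift <- layer$params$beta - scale * layer$runMean
    list(y = .chanAffine(x, scale, shift), cache = NULL)
  }
}

bnBw <- function(layer, cache, dy) {
  g <- .bnBackward(cache$x, dy, layer$params$gamma, cache$mu, cache$invstd)
  layer$grads$gamma <- layer$grads$gamma + g$dgamma
  layer$grads$beta <- layer$grads$beta + g$dbeta
  g$dx
}

reluFw <- function(x) {
  y <- .reluForward(x)
  list(y = y, cache = y)
}

reluBw <- function(cache, dy) {
  .reluBackward(cache, dy)
}

poolFw <- function(x) {
  r <- .maxPool2Forward(x)
  list(y = r$y, cache = list(idx = r$idx, dims = dim(x)))
}

poolBw <- function(cache, dy) {
  .maxPool2Backward(dy, cache$idx, cache$dims)
}

catChannels <- function(a, b) .catChannels(a, b)

splitChannels <- function(x, c1) .splitChannels(x, as.integer(c1))

sigmoidFw <- function(x) 1 / (1 + exp(-x))

layerParamCount <- function(layer) {
  sum(vapply(layer$params, length, integer(1)))
}
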