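# Internal helpers shared across modules.

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-item child seed from a master seed; stays within 32-bit range.
childSeed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

stopIfNot <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Clip to [0, 255] and round, preserving matrix shape (pmin/pmax would drop
# the dim attribute when the scalar comes first).
clip8bit <- function(m) {
  m[m < 0] <- 0
  m[m > 255] <- 255
  round(m)
}

# Coerce any numeric/logical matrix to strict 0/1 integer.
asBinaryMask <- function(mask) {
  stopIfNot(is.matrix(mask), "mask must be a matrix")
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  m
}
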