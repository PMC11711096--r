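# Internal helpers shared across modules.

#' @keywords internal
logistic <- function(x) 1 / (1 + exp(-x))

#' @keywords internal
clamp <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

# Robust standard deviation: 1.4826 * median absolute deviation, the scaling
# that matches the SD of a normal distribution.
#' @keywords internal
robust_sd <- function(x) 1.4826 * stats::median(abs(x - stats::median(x)))

# Derive a per-stream 31-bit seed from a global seed and stream labels, so that
# per-cell / per-trial random streams are stable when other streams are added.
#' @keywords internal
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  # multiplier kept small so h * 69069 stays exactly representable in a double
  for (v in ids) h <- (h * 69069 + as.numeric(v) + 12345) %% 2147483647
  as.integer(h)
}

#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Pixel-centre coordinates (micrometres) for a frame of given shape, following
# the package convention: x rightward, y downward, origin at the image centre.
#' @keywords internal
pixel_coords <- function(shape, pixel_pitch) {
  ny <- shape[1]; nx <- shape[2]
  x <- (seq_len(nx) - (nx + 1) / 2) * pixel_pitch
  y <- (seq_len(ny) - (ny + 1) / 2) * pixel_pitch
  list(x = x, y = y)
}

#' @keywords internal
stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
}

# Shoelace polygon area (absolute value).
#' @keywords internal
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}
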