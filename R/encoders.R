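# Ground-truth encoders and Poisson response simulation.
#
# Three encoder families are supported, mirroring the model classes the
# analysis fits: a plain LN encoder (arbitrary pixel-space spatial filter +
# static nonlinearity), a DoG LN encoder (parametric spatial DoG + logistic
# output), and a subunit-grid encoder (weighted rectified DoG subunits pooled
# through a Naka-Rushton output). Encoders arranged in a mosaic make up a
# ground-truth population from which spike rasters are simulated.

#' Naka-Rushton output nonlinearity
#'
#' `G(x) = a * x^n / (x^n + k^n) + b`, evaluated for `x >= 0` with
#' non-negative parameters.
#'
#' @param x Non-negative input.
#' @param out List or vector with elements `a`, `b`, `n`, `k` (set `b = 0` for
#'   the variant without baseline).
#' @return `G(x)`.
#' @export
naka_rushton <- function(x, out) {
  a <- out[["a"]]; b <- if (!is.null(out[["b"]])) out[["b"]] else 0
  n <- out[["n"]]; k <- out[["k"]]
  x <- pmax(x, 0)
  xn <- x^n
  ifelse(x == 0, b, a * xn / (xn + k^n) + b)
}

#' LN encoder
#'
#' A linear spatial filter (optionally with a temporal kernel over stimulus
#' frames) followed by a static output nonlinearity, producing a firing rate.
#'
#' @param spatial_filter Matrix of filter weights on the stimulus pixel grid.
#' @param temporal_kernel Kernel over frame lags (lag 0 first); default is an
#'   instantaneous response.
#' @param nonlinearity One of `"softplus"`, `"exp"`, `"logistic"`, `"linear"`
#'   (the latter rectified at zero to keep rates non-negative).
#' @param gain,threshold Input scaling and offset applied before the
#'   nonlinearity.
#' @param rate_scale Output firing-rate scale (Hz).
#' @param centre Encoder centre `c(x, y)` in µm (bookkeeping for mosaics).
#' @param cell_id Optional label.
#' @return Object of class `c("ln_encoder", "encoder")`.
#' @export
ln_encoder <- function(spatial_filter, temporal_kernel = 1,
                       nonlinearity = c("softplus", "exp", "logistic", "linear"),
                       gain = 1, threshold = 0, rate_scale = 20,
                       centre = c(0, 0), cell_id = NULL) {
  nonlinearity <- match.arg(nonlinearity)
  structure(list(spatial_filter = spatial_filter,
                 temporal_kernel = temporal_kernel,
                 nonlinearity = nonlinearity, gain = gain,
                 threshold = threshold, rate_scale = rate_scale,
                 centre = centre, cell_id = cell_id),
            class = c("ln_encoder", "encoder"))
}

#' DoG LN encoder
#'
#' Firing rate `R = a * logistic(beta * r_dog + gamma)` where `r_dog` is the
#' DoG activation of the stimulus (analytic for gratings, pixel-space dot
#' product otherwise).
#'
#' @param spatial A [dog_spatial()].
#' @param beta,gamma Steepness and threshold of the logistic output.
#' @param a Rate scale: spikes per flash for flashed stimuli, Hz otherwise.
#' @param temporal_kernel Causal kernel over frame lags (lag 0 first) applied
#'   to the spatial drive for frame-based stimuli; scalar 1 for an
#'   instantaneous response.
#' @param cell_id Optional label.
#' @return Object of class `c("dog_ln_encoder", "encoder")`.
#' @export
dog_ln_encoder <- function(spatial, beta = 4, gamma = -1, a = 5,
                           temporal_kernel = 1, cell_id = NULL) {
  stopifnot(inherits(spatial, "dog_spatial"), a > 0)
  structure(list(spatial = spatial, beta = beta, gamma = gamma, a = a,
                 temporal_kernel = temporal_kernel,
                 centre = c(spatial$x0, spatial$y0), cell_id = cell_id),
            class = c("dog_ln_encoder", "encoder"))
}

#' Subunit-grid encoder
#'
#' Firing rate `R = G(sum_s w_s * logistic(beta * r_s + gamma))` with circular
#' DoG subunits at the given centres and a Naka-Rushton output `G`.
#'
#' @param centres Two-column matrix of subunit centres (µm).
#' @param w Non-negative subunit weights (one per centre).
#' @param sigma Subunit centre Gaussian SD (µm, shared).
#' @param k_s,w_surr Subunit surround scale and strength (shared).
#' @param beta,gamma Subunit logistic nonlinearity parameters.
#' @param out Naka-Rushton parameters, list `(a, b, n, k)`.
#' @param temporal_kernel Causal kernel over frame lags applied to every
#'   subunit activation before the subunit nonlinearity (frame-based
#'   stimuli); scalar 1 for an instantaneous response.
#' @param cell_id Optional label.
#' @return Object of class `c("sg_encoder", "encoder")`.
#' @export
sg_encoder <- function(centres, w, sigma = 15, k_s = 2, w_surr = 0.2,
                       beta = 4, gamma = -2,
                       out = list(a = 6, b = 0.1, n = 2, k = 1),
                       temporal_kernel = 1, cell_id = NULL) {
  centres <- as.matrix(centres)
  stopifnot(ncol(centres) == 2, length(w) == nrow(centres), all(w >= 0))
  structure(list(centres = centres, w = w, sigma = sigma, k_s = k_s,
                 w_surr = w_surr, beta = beta, gamma = gamma, out = out,
                 temporal_kernel = temporal_kernel,
                 centre = colSums(centres * w) / sum(w), cell_id = cell_id),
            class = c("sg_encoder", "encoder"))
}

# causal convolution of columns of a (frames x k) matrix with a lag kernel
#' @keywords internal
conv_frames <- function(m, kernel) {
  if (length(kernel) == 1) return(m * kernel)
  m <- as.matrix(m)
  out <- matrix(0, nrow(m), ncol(m))
  for (l in seq_along(kernel)) {
    idx <- seq_len(nrow(m) - l + 1L)
    out[idx + l - 1L, ] <- out[idx + l - 1L, ] + kernel[l] * m[idx, , drop = FALSE]
  }
  out
}

# ---- drive / rate evaluation -----------------------------------------------

# Linear drive of an LN encoder for a stack of frames given as a matrix
# (frames x pixels); applies the temporal kernel along frames.
#' @keywords internal
ln_drive <- function(enc, frame_mat) {
  drive <- as.numeric(frame_mat %*% as.numeric(enc$spatial_filter))
  k <- enc$temporal_kernel
  if (length(k) > 1) {
    n <- length(drive)
    out <- numeric(n)
    for (l in seq_along(k)) {
      idx <- seq_len(n) - (l - 1L)
      ok <- idx >= 1
      out[ok] <- out[ok] + k[l] * drive[idx[ok]]
    }
    drive <- out
  } else drive <- k * drive
  drive
}

#' @keywords internal
apply_output_nl <- function(enc, drive) {
  z <- enc$gain * drive + enc$threshold
  y <- switch(enc$nonlinearity,
              softplus = log1p(exp(pmin(z, 30))),
              exp = exp(pmin(z, 30)),
              logistic = logistic(z),
              linear = pmax(z, 0))
  enc$rate_scale * y
}

#' Encoder firing rate for a stimulus
#'
#' Computes the noise-free rate trace of an encoder for a stimulus set. For
#' grating batteries the analytic DoG formulas are used; for checkerboards,
#' videos and flashed images the pixel-space filters are applied.
#'
#' @param enc An encoder.
#' @param stim A `stimulus_set`.
#' @param mode Amplitude exponent mode for grating responses (see
#'   [dog_grating_response()]).
#' @return Numeric vector of rates: spikes per flash for flashed stimuli
#'   (one entry per scheduled flash), otherwise Hz per frame.
#' @export
encoder_rate <- function(enc, stim, mode = "exact") {
  UseMethod("encoder_rate")
}

#' @export
encoder_rate.dog_ln_encoder <- function(enc, stim, mode = "exact") {
  if (stim$kind == "flashed_gratings") {
    r <- dog_battery_response(enc$spatial, stim$gratings, mode = mode)$response
    rate_per_id <- enc$a * logistic(enc$beta * r + enc$gamma)
    rate_per_id[stim$schedule$grating_id]
  } else {
    fm <- stimulus_frame_matrix(stim)
    filt <- dog_filter_image(enc$spatial, attr(fm, "shape"), attr(fm, "pitch"))
    drive <- as.numeric(conv_frames(fm %*% as.numeric(filt),
                                    enc$temporal_kernel %||% 1))
    enc$a * logistic(enc$beta * drive + enc$gamma)
  }
}

#' @export
encoder_rate.sg_encoder <- function(enc, stim, mode = "exact") {
  if (stim$kind == "flashed_gratings") {
    act <- sg_grating_activations(enc, stim$gratings, mode = mode)
    pooled <- as.numeric(logistic(enc$beta * act + enc$gamma) %*% enc$w)
    naka_rushton(pooled, enc$out)[stim$schedule$grating_id]
  } else {
    fm <- stimulus_frame_matrix(stim)
    filt <- sg_filter_matrix(enc, attr(fm, "shape"), attr(fm, "pitch"))
    act <- conv_frames(fm %*% filt, enc$temporal_kernel %||% 1)
    pooled <- as.numeric(logistic(enc$beta * act + enc$gamma) %*% enc$w)
    naka_rushton(pooled, enc$out)
  }
}

#' @export
encoder_rate.ln_encoder <- function(enc, stim, mode = "exact") {
  fm <- stimulus_frame_matrix(stim)
  apply_output_nl(enc, ln_drive(enc, fm))
}

# Subunit activations (gratings x subunits) for a grating table.
#' @keywords internal
sg_grating_activations <- function(enc, gratings, mode = "exact") {
  c0 <- amp_const(mode)
  f <- gratings$f
  A <- exp(-c0 * enc$sigma^2 * f^2) -
    enc$w_surr * exp(-c0 * (enc$k_s * enc$sigma)^2 * f^2)
  cosv <- sg_cos_theta(enc$centres, gratings)
  A * cosv
}

# cos(Theta) per (grating, subunit centre); gratings x centres matrix.
#' @keywords internal
sg_cos_theta <- function(centres, gratings) {
  kx <- 2 * pi * gratings$f * cos(gratings$theta)
  ky <- 2 * pi * gratings$f * sin(gratings$theta)
  arg <- outer(kx, centres[, 1]) + outer(ky, centres[, 2]) +
    gratings$phi - pi / 2
  cos(arg)
}

# Pixel-space subunit filters as a (pixels x subunits) matrix.
#' @keywords internal
sg_filter_matrix <- function(enc, shape, pitch) {
  vapply(seq_len(nrow(enc$centres)), function(s) {
    sp <- dog_spatial(x0 = enc$centres[s, 1], y0 = enc$centres[s, 2],
                      sigma_x = enc$sigma, sigma_y = enc$sigma,
                      theta_dog = 0, k_s = enc$k_s, w_surr = enc$w_surr)
    as.numeric(dog_filter_image(sp, shape, pitch))
  }, numeric(prod(shape)))
}

# Stack stimulus frames into a (frames x pixels) matrix with shape/pitch
# attributes. Flashed images contribute one row per scheduled flash.
#' @keywords internal
stimulus_frame_matrix <- function(stim) {
  if (stim$kind == "checkerboard") {
    d <- dim(stim$frames)
    m <- matrix(stim$frames, d[1], d[2] * d[3])
    attr(m, "shape") <- d[2:3]; attr(m, "pitch") <- stim$pixel_pitch
    m
  } else if (stim$kind == "video") {
    nfr <- nrow(stim$schedule)
    m <- t(vapply(seq_len(nfr), function(t) as.numeric(video_frame(stim, t)),
                  numeric(prod(stim$crop))))
    attr(m, "shape") <- stim$crop; attr(m, "pitch") <- stim$pixel_pitch
    m
  } else if (stim$kind == "flashed_images") {
    sh <- dim(stim$images[[1]])
    m <- t(vapply(stim$schedule$image_id,
                  function(i) as.numeric(stim$images[[i]]), numeric(prod(sh))))
    attr(m, "shape") <- sh; attr(m, "pitch") <- stim$pixel_pitch
    m
  } else stop("no frame matrix for stimulus kind ", stim$kind)
}

# ---- population and spike simulation ---------------------------------------

#' Hexagonal mosaic of centre positions
#'
#' @param n_rings Number of hexagonal rings around the origin (0 gives one
#'   point).
#' @param spacing Centre-to-centre distance (µm).
#' @param centre Offset `c(x, y)` in µm.
#' @return Two-column matrix of `(x, y)` positions.
#' @export
hex_mosaic <- function(n_rings = 2, spacing = 150, centre = c(0, 0)) {
  pts <- matrix(0, 1, 2)
  for (q in -n_rings:n_rings) for (r in -n_rings:n_rings) {
    s <- -q - r
    if (max(abs(c(q, r, s))) <= n_rings && !(q == 0 && r == 0)) {
      x <- spacing * (q + r / 2)
      y <- spacing * r * sqrt(3) / 2
      pts <- rbind(pts, c(x, y))
    }
  }
  sweep(pts, 2, centre, `+`)
}

#' Ground-truth population
#'
#' Bundles encoders with their mosaic centres.
#'
#' @param encoders List of encoder objects; `cell_id`s default to their index.
#' @return Object of class `ground_truth_population`.
#' @export
population <- function(encoders) {
  for (i in seq_along(encoders))
    if (is.null(encoders[[i]]$cell_id)) encoders[[i]]$cell_id <- i
  centres <- t(vapply(encoders, function(e) as.numeric(e$centre), numeric(2)))
  if (anyDuplicated(centres)) warning("duplicate encoder centres in mosaic")
  structure(list(encoders = encoders, centres = centres),
            class = "ground_truth_population")
}

#' Spike raster container
#'
#' Per-cell, per-trial binned spike counts. Bins are half-open `[t, t + dt)`
#' and left-aligned to stimulus onsets.
#'
#' @param counts Integer matrix, trials x bins.
#' @param bin_width Bin width in seconds.
#' @param t0 Time of the left edge of bin 1 on the stimulus clock (s).
#' @param cell_id Cell label.
#' @return Object of class `spike_raster`.
#' @export
spike_raster <- function(counts, bin_width, t0 = 0, cell_id = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("spike counts must be non-negative integers")
  structure(list(counts = counts, bin_width = bin_width, t0 = t0,
                 cell_id = cell_id),
            class = "spike_raster")
}

#' Simulate Poisson spike responses
#'
#' Draws spike counts independently per bin and trial from a Poisson
#' distribution with mean `rate * bin_width` (or mean equal to the rate
#' directly, for flashed stimuli where rates are spikes per flash).
#' Deterministic given the seed; per-cell and per-trial random streams are
#' derived by seed splitting, so adding cells or trials does not reshuffle
#' existing ones.
#'
#' @param pop A [population()].
#' @param stim A `stimulus_set`.
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @param bin_width Bin width in seconds; defaults to one stimulus frame (for
#'   flashed stimuli the flash is the bin and `bin_width` is ignored).
#' @param mode Grating amplitude mode passed to [encoder_rate()].
#' @return A list of [spike_raster()] objects, one per cell, each carrying the
#'   noise-free `rate` as an attribute.
#' @export
simulate_responses <- function(pop, stim, n_trials = 1, seed = 1,
                               bin_width = NULL, mode = "exact") {
  flashed <- stim$kind %in% c("flashed_gratings", "flashed_images")
  if (is.null(bin_width)) bin_width <- 1 / stim$frame_rate
  lapply(seq_along(pop$encoders), function(ci) {
    enc <- pop$encoders[[ci]]
    rate <- encoder_rate(enc, stim, mode = mode)
    if (any(rate < 0) || !all(is.finite(rate)))
      stop(sprintf("encoder %s produced negative or non-finite rates",
                   as.character(enc$cell_id)))
    mu <- if (flashed) rate else rate * bin_width
    counts <- t(vapply(seq_len(n_trials), function(tr) {
      with_seed(derive_seed(seed, 7000L, ci, tr),
                stats::rpois(length(mu), mu))
    }, numeric(length(mu))))
    r <- spike_raster(counts, bin_width = if (flashed) NA_real_ else bin_width,
                      cell_id = enc$cell_id)
    attr(r, "rate") <- rate
    r
  })
}

#' Re-bin a rate trace to finer time bins
#'
#' Expands a per-frame rate (Hz) into bins of width `bin_width` by piecewise-
#' constant interpolation, for fine-timescale Poisson simulation (for example
#' 0.4 ms bins for the information-rate analysis).
#'
#' @param rate Per-frame rate in Hz.
#' @param frame_rate Frame rate in Hz.
#' @param bin_width Target bin width in seconds.
#' @return Rate vector at the finer resolution.
#' @export
upsample_rate <- function(rate, frame_rate, bin_width) {
  t_total <- length(rate) / frame_rate
  n_bins <- floor(t_total / bin_width)
  idx <- pmin(floor((seq_len(n_bins) - 0.5) * bin_width * frame_rate) + 1L,
              length(rate))
  rate[idx]
}
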