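# White-noise receptive-field characterization: spike-triggered average,
# separation into spatial and temporal filters, receptive-field contours,
# and basic response-quality metrics.

#' Spike-triggered average from a checkerboard stimulus
#'
#' Computes the spatiotemporal STA over a lag window (500 ms by default)
#' preceding each spike bin: `STA[lag, , ]` is the spike-count-weighted mean
#' stimulus frame `lag - 1` frames before the spike. Spikes earlier than one
#' full lag window into the stimulus are discarded.
#'
#' @param stim A `stimulus_set` of kind `"checkerboard"`.
#' @param raster A [spike_raster()] binned at the stimulus update rate
#'   (trials x frames).
#' @param window_s Length of the lag window in seconds.
#' @return A list of class `sta` with `sta` (array `n_lags x ny x nx`, lag 1 =
#'   the spike frame), `n_spikes`, and the stimulus geometry.
#' @export
compute_sta <- function(stim, raster, window_s = 0.5) {
  stopifnot(stim$kind == "checkerboard")
  n_lags <- round(window_s * stim$frame_rate)
  counts <- colSums(raster$counts)  # spikes per frame, pooled over trials
  nfr <- min(length(counts), dim(stim$frames)[1])
  counts <- counts[seq_len(nfr)]
  usable <- counts
  usable[seq_len(min(n_lags - 1, nfr))] <- 0
  n_spikes <- sum(usable)
  if (n_spikes < 1)
    stop("no usable spikes after the first lag window; cannot compute STA")
  d <- dim(stim$frames)
  fm <- matrix(stim$frames[seq_len(nfr), , ], nfr, d[2] * d[3])
  sta <- array(0, dim = c(n_lags, d[2], d[3]))
  for (l in seq_len(n_lags)) {
    w <- c(usable[l:nfr], rep(0, l - 1L))  # weight for frame t is count at t+l-1
    sta[l, , ] <- matrix(crossprod(fm, w) / n_spikes, d[2], d[3])
  }
  structure(list(sta = sta, n_spikes = n_spikes, n_lags = n_lags,
                 pixel_pitch = stim$pixel_pitch, frame_rate = stim$frame_rate),
            class = "sta")
}

#' Separate an STA into spatial and temporal filters
#'
#' The temporal filter is the average time course of stixels whose absolute
#' peak exceeds `threshold` robust standard deviations (1.4826 x median
#' absolute deviation) of all STA elements; the spatial filter is the
#' projection of the STA onto the unit-normalized temporal filter. The
#' temporal filter is normalized to unit norm with its extremum positive; the
#' spatial filter carries the residual sign and scale.
#'
#' @param sta An [compute_sta()] result, or a bare array `lags x ny x nx`.
#' @param threshold Robust-SD multiple for stixel selection.
#' @return List with `spatial` (matrix), `temporal` (vector over lags, lag 1 =
#'   spike frame), and `selected` (logical matrix of stixels used).
#' @export
separate_filters <- function(sta, threshold = 4.5) {
  a <- if (inherits(sta, "sta")) sta$sta else sta
  stopifnot_finite(a, "STA")
  rsd <- robust_sd(as.numeric(a))
  if (rsd == 0)
    stop("robust SD of STA elements is zero; stixel threshold is degenerate")
  peak <- apply(abs(a), c(2, 3), max)
  selected <- peak > threshold * rsd
  if (!any(selected))
    stop(sprintf("no stixel exceeds %.1f robust SDs; cannot extract filters",
                 threshold))
  n_lags <- dim(a)[1]
  am <- matrix(a, n_lags, dim(a)[2] * dim(a)[3])
  temporal <- rowMeans(am[, as.numeric(selected) > 0, drop = FALSE])
  if (abs(min(temporal)) > abs(max(temporal))) temporal <- -temporal
  temporal <- temporal / sqrt(sum(temporal^2))
  spatial <- matrix(crossprod(am, temporal), dim(a)[2], dim(a)[3])
  list(spatial = spatial, temporal = temporal, selected = selected)
}

# Bilinear upsampling of a matrix by an integer factor (to single-pixel
# resolution), sampling at the upsampled pixel centres.
#' @keywords internal
upsample_bilinear <- function(m, factor) {
  ny <- nrow(m); nx <- ncol(m)
  yo <- (seq_len(ny * factor) - 0.5) / factor + 0.5 - 0.5 / factor
  xo <- (seq_len(nx * factor) - 0.5) / factor + 0.5 - 0.5 / factor
  yi <- clamp(yo, 1, ny); xi <- clamp(xo, 1, nx)
  y0 <- clamp(floor(yi), 1, ny - 1); x0 <- clamp(floor(xi), 1, nx - 1)
  wy <- yi - y0; wx <- xi - x0
  m[y0, x0] * outer(1 - wy, 1 - wx) + m[y0 + 1, x0] * outer(wy, 1 - wx) +
    m[y0, x0 + 1] * outer(1 - wy, wx) + m[y0 + 1, x0 + 1] * outer(wy, wx)
}

# Separable Gaussian blur with reflective boundaries.
#' @keywords internal
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(4 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  blur1 <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(min(r, n))]), v, rev(v[seq.int(max(1, n - r + 1), n)]))
    stats::filter(vp, k, sides = 2)[r + seq_len(n)]
  }
  m2 <- apply(m, 2, blur1)
  t(apply(m2, 1, blur1))
}

#' Receptive-field contour, centre and area
#'
#' Upsamples the spatial filter to single-pixel resolution (bilinear), blurs
#' it with a circular Gaussian (`sigma_blur_px` pixels of the upsampled grid),
#' and extracts the level set at `level` (25% by default) of the blurred
#' maximum. When several closed contours exist, the one enclosing the peak is
#' kept. Contour points whose neighbour distance exceeds `triage_sd` robust
#' standard deviations of all neighbour distances are removed. The centre is
#' the coordinate-wise median of the contour points and the area the enclosed
#' polygon area.
#'
#' @param spatial Spatial filter matrix (stixel grid).
#' @param pixel_pitch Stixel side in µm.
#' @param target_pitch Pixel size of the upsampled grid in µm (upsampling
#'   factor is `round(pixel_pitch / target_pitch)`).
#' @param sigma_blur_px Gaussian blur SD in upsampled pixels.
#' @param level Contour level as a fraction of the blurred maximum.
#' @param triage_sd Robust-SD multiple for the neighbour-distance triage.
#' @return List with `contour` (two-column matrix of x/y in µm), `centre`
#'   (µm), `area` (µm²) and the blurred upsampled filter.
#' @export
extract_contour <- function(spatial, pixel_pitch, target_pitch = pixel_pitch / 4,
                            sigma_blur_px = 4, level = 0.25, triage_sd = 20) {
  if (max(spatial) <= 0) spatial <- -spatial  # contour the dominant lobe
  factor <- max(1L, round(pixel_pitch / target_pitch))
  up <- upsample_bilinear(spatial, factor)
  bl <- gaussian_blur(up, sigma_blur_px)
  pitch_up <- pixel_pitch / factor
  co <- pixel_coords(dim(bl), pitch_up)
  lev <- level * max(bl)
  cl <- grDevices::contourLines(x = co$y, y = co$x, z = bl, levels = lev)
  if (!length(cl)) stop("empty level set at the requested contour level")
  peak <- which(bl == max(bl), arr.ind = TRUE)[1, ]
  peak_xy <- c(co$x[peak[2]], co$y[peak[1]])
  pick <- 1L
  if (length(cl) > 1) {
    inside <- vapply(cl, function(cc) {
      point_in_polygon(peak_xy[1], peak_xy[2], cc$y, cc$x)
    }, logical(1))
    pick <- if (any(inside)) which(inside)[1] else
      which.max(vapply(cl, function(cc) polygon_area(cc$y, cc$x), numeric(1)))
  }
  cx <- cl[[pick]]$y; cy <- cl[[pick]]$x  # contourLines: x = rows here
  d <- sqrt(diff(cx)^2 + diff(cy)^2)
  if (length(d) > 3) {
    rsd <- robust_sd(d)
    if (rsd > 0) {
      bad_seg <- d > triage_sd * rsd
      bad_pt <- c(FALSE, bad_seg) & c(bad_seg, FALSE)  # point with two long edges
      cx <- cx[!bad_pt]; cy <- cy[!bad_pt]
    }
  }
  centre <- c(stats::median(cx), stats::median(cy))
  list(contour = cbind(x_um = cx, y_um = cy), centre = centre,
       area = polygon_area(cx, cy), blurred = bl)
}

#' @keywords internal
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx); j <- n; inside <- FALSE
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py) &&
        px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- !inside
    j <- i
  }
  inside
}

#' Symmetrized coefficient of determination
#'
#' Mean of `R²(a predicts b)` and `R²(b predicts a)` where
#' `R² = 1 - SS_res / SS_tot`. Symmetric in its arguments, equal to 1 iff the
#' inputs are identical, and can be negative.
#'
#' @param rate_a,rate_b Equal-length numeric vectors (e.g. firing-rate
#'   profiles of even vs odd trials).
#' @return Scalar symmetrized R².
#' @export
symmetrized_r2 <- function(rate_a, rate_b) {
  stopifnot(length(rate_a) == length(rate_b), length(rate_a) >= 2)
  va <- sum((rate_a - mean(rate_a))^2)
  vb <- sum((rate_b - mean(rate_b))^2)
  if (va == 0 || vb == 0)
    stop("symmetrized R2 undefined for zero-variance input")
  ss <- sum((rate_a - rate_b)^2)
  ((1 - ss / vb) + (1 - ss / va)) / 2
}

#' Even/odd (or first/second half) trial split rates
#'
#' @param raster A [spike_raster()].
#' @param by `"parity"` (even vs odd trial index, 0-based) or `"half"`
#'   (first `floor(n/2)` trials vs the rest).
#' @return List of two trial-averaged rate vectors.
#' @export
split_trial_rates <- function(raster, by = c("parity", "half")) {
  by <- match.arg(by)
  n <- nrow(raster$counts)
  idx <- if (by == "parity") ((seq_len(n) - 1L) %% 2L == 0L)
         else seq_len(n) <= n %/% 2L
  list(a = colMeans(raster$counts[idx, , drop = FALSE]),
       b = colMeans(raster$counts[!idx, , drop = FALSE]))
}

#' Fano factors per fixation
#'
#' For each fixation, the Fano factor of the fixation spike count (across-
#' trial variance over mean). Fixations with a mean below `min_mean_spikes`
#' (3 by default) are excluded; the summary is the mean over surviving
#' fixations weighted by the mean spike count. Callers should gate cells on a
#' positive first-half/second-half symmetrized R² to exclude non-stationary
#' activity.
#'
#' @param raster A [spike_raster()] with at least 2 trials, binned at the
#'   frame rate.
#' @param fixations A fixation table from [detect_fixations()] (uses
#'   `start_frame`/`end_frame`).
#' @param min_mean_spikes Exclusion threshold on the mean fixation spike
#'   count.
#' @return List with `per_fixation` (data.frame: fixation, mean_count, fano,
#'   included) and `fano_weighted` (NA with a message attribute when no
#'   fixation survives).
#' @export
fano_per_fixation <- function(raster, fixations, min_mean_spikes = 3) {
  stopifnot(nrow(raster$counts) >= 2)
  per <- lapply(seq_len(nrow(fixations)), function(i) {
    fr <- seq.int(fixations$start_frame[i], fixations$end_frame[i] - 1L)
    tot <- rowSums(raster$counts[, fr, drop = FALSE])
    m <- mean(tot)
    data.frame(fixation = i, mean_count = m,
               fano = if (m > 0) stats::var(tot) / m else NA_real_,
               included = m >= min_mean_spikes)
  })
  per <- do.call(rbind, per)
  keep <- per$included & is.finite(per$fano)
  fw <- if (any(keep))
    sum(per$fano[keep] * per$mean_count[keep]) / sum(per$mean_count[keep])
  else NA_real_
  list(per_fixation = per, fano_weighted = fw)
}
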