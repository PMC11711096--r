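# Fixation segmentation of gaze traces, spatial contrast inside receptive
# fields, partial-correlation decompositions of pairwise response
# correlations, correlation-distance curves, stimulus decorrelation, and
# direction-selectivity metrics.

#' Detect fixations from a gaze trace
#'
#' Image transitions always mark a fixation boundary. Within each image
#' presentation, the instantaneous gaze speed (distance between consecutive
#' positions times the frame rate) is scanned for local maxima above an
#' amplitude threshold; peaks closer than the minimum peak interval are
#' resolved in favour of the taller peak. Every retained peak splits the
#' ongoing fixation.
#'
#' @param trace A `gaze_trace` (from [make_gaze_video()]) or a two-column
#'   matrix of gaze positions in µm.
#' @param frame_rate Frame rate in Hz (taken from the trace if present).
#' @param transitions Frame indices at which a new image appears (always
#'   boundaries); frame 1 is implied.
#' @param min_interval_ms Minimum peak time interval (47 ms marmoset, 53 ms
#'   mouse in the reference setup).
#' @param min_amplitude Velocity threshold; in deg/s if
#'   `retinal_magnification` is given (10 deg/s marmoset, 300 deg/s mouse),
#'   otherwise in µm/s.
#' @param retinal_magnification µm per degree (100 marmoset, 31 mouse), or
#'   `NULL` if `min_amplitude` is already in µm/s.
#' @return A `fixation_table` data.frame with columns `fixation`,
#'   `start_frame`, `end_frame` (half-open), `source` (`"transition"` or
#'   `"saccade"` for the boundary that opened the fixation), and an attribute
#'   `saccade_frames` with the retained velocity peaks.
#' @export
detect_fixations <- function(trace, frame_rate = NULL, transitions = NULL,
                             min_interval_ms = 47, min_amplitude = 10,
                             retinal_magnification = 100) {
  pos <- if (inherits(trace, "gaze_trace")) trace$positions else as.matrix(trace)
  if (is.null(frame_rate)) frame_rate <- trace$frame_rate
  n <- nrow(pos)
  if (n < 1) stop("empty gaze trace")
  thresh_um_s <- if (is.null(retinal_magnification)) min_amplitude
                 else min_amplitude * retinal_magnification
  speed <- c(0, sqrt(rowSums(diff(pos)^2)) * frame_rate)  # µm/s at each frame
  if (is.null(transitions)) transitions <- 1L
  transitions <- sort(unique(c(1L, transitions)))
  min_dist <- round(min_interval_ms / 1000 * frame_rate)
  peaks <- integer(0)
  # peak finding restricted to within-image segments
  bounds <- c(transitions, n + 1L)
  for (b in seq_len(length(bounds) - 1L)) {
    seg <- bounds[b]:(bounds[b + 1L] - 1L)
    v <- speed[seg]
    if (length(v) < 3) next
    cand <- which(v[-c(1, length(v))] > v[-c(length(v) - 1, length(v))] &
                    v[-c(1, length(v))] >= v[-(1:2)]) + 1L
    cand <- cand[v[cand] >= thresh_um_s]
    if (!length(cand)) next
    cand <- cand[order(-v[cand], cand)]
    kept <- integer(0)
    for (p in cand) {
      if (!length(kept) || all(abs(kept - p) >= min_dist)) kept <- c(kept, p)
    }
    peaks <- c(peaks, seg[sort(kept)])
  }
  starts <- sort(unique(c(transitions, peaks)))
  ends <- c(starts[-1], n + 1L)
  out <- data.frame(fixation = seq_along(starts), start_frame = starts,
                    end_frame = ends,
                    source = ifelse(starts %in% peaks, "saccade", "transition"))
  attr(out, "saccade_frames") <- peaks
  class(out) <- c("fixation_table", "data.frame")
  out
}

#' Spatial contrast and linear activation per fixation
#'
#' Spatial contrast of a frame is the standard deviation of its pixels inside
#' the receptive field, weighted by the receptive-field profile (the positive
#' part of the normalized spatial filter). Linear activation is the output of
#' the signed spatial filter. Each fixation is assigned the median over its
#' frames.
#'
#' @param video A `stimulus_set` of kind `"video"` (or a `frames x pixels`
#'   matrix from [stimulus_frame_matrix()]).
#' @param fixations A `fixation_table`.
#' @param spatial_filter Spatial filter matrix at the video resolution.
#' @return Data frame with `fixation`, `spatial_contrast`,
#'   `linear_activation`, plus per-frame vectors as attributes `sc_frame`,
#'   `act_frame`.
#' @export
spatial_contrast_and_activation <- function(video, fixations, spatial_filter) {
  fm <- if (is.matrix(video)) video else stimulus_frame_matrix(video)
  if (max(fixations$end_frame) - 1L > nrow(fm))
    stop("fixation extends beyond the video")
  filt <- as.numeric(spatial_filter)
  wpos <- pmax(filt, 0)
  if (sum(wpos) == 0) stop("receptive-field profile has no positive part")
  wpos <- wpos / sum(wpos)
  mu_w <- as.numeric(fm %*% wpos)
  ex2 <- as.numeric(fm^2 %*% wpos)
  sc_frame <- sqrt(pmax(ex2 - mu_w^2, 0))
  act_frame <- as.numeric(fm %*% filt)
  per_fix <- function(v) vapply(seq_len(nrow(fixations)), function(i)
    stats::median(v[seq.int(fixations$start_frame[i],
                            fixations$end_frame[i] - 1L)]), numeric(1))
  out <- data.frame(fixation = fixations$fixation,
                    spatial_contrast = per_fix(sc_frame),
                    linear_activation = per_fix(act_frame))
  attr(out, "sc_frame") <- sc_frame
  attr(out, "act_frame") <- act_frame
  out
}

#' Split fixations into high- and low-spatial-contrast groups
#'
#' Balances light-level effects: fixations are sorted by the linear
#' activation averaged across the two cells, neighbouring fixations in the
#' sorted list are paired (an odd final fixation is dropped), and within each
#' pair the fixation with the higher average spatial contrast joins the
#' high-spatial-contrast group (ties: the earlier fixation index).
#'
#' @param fix_a,fix_b Per-fixation tables from
#'   [spatial_contrast_and_activation()] for the two cells.
#' @return List with `high` and `low` (fixation indices, equal sizes) and
#'   `n_pairs`.
#' @export
split_by_spatial_contrast <- function(fix_a, fix_b) {
  n <- nrow(fix_a)
  if (n < 2) stop("need at least 2 fixations")
  act <- (fix_a$linear_activation + fix_b$linear_activation) / 2
  sc <- (fix_a$spatial_contrast + fix_b$spatial_contrast) / 2
  ord <- order(act, seq_len(n))
  if (length(ord) %% 2 == 1) ord <- ord[-length(ord)]
  high <- integer(0); low <- integer(0)
  for (p in seq_len(length(ord) / 2)) {
    i <- ord[2 * p - 1]; j <- ord[2 * p]
    hi_first <- sc[i] > sc[j] || (sc[i] == sc[j] && i < j)
    if (hi_first) { high <- c(high, i); low <- c(low, j) }
    else { high <- c(high, j); low <- c(low, i) }
  }
  list(high = sort(high), low = sort(low), n_pairs = length(high))
}

#' Partial correlation over a frame subset
#'
#' The numerator of the Pearson correlation restricted to a subset of frames,
#' with means and standard deviations taken over the entire segment:
#' `r_subset = sum_{i in subset} (x_i - xbar)(y_i - ybar) /
#' ((N - 1) * sd_x * sd_y)`. Partial correlations over complementary subsets
#' sum exactly to the full Pearson correlation.
#'
#' @param x,y Firing-rate vectors over the full segment.
#' @param subset Frame indices (possibly empty).
#' @return Scalar partial correlation.
#' @export
partial_correlation <- function(x, y, subset) {
  stopifnot(length(x) == length(y))
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("zero variance over the full segment")
  if (!length(subset)) return(0)
  sum((x[subset] - mean(x)) * (y[subset] - mean(y))) /
    ((length(x) - 1) * sx * sy)
}

#' Decompose a pairwise correlation over fixation groups
#'
#' @param x,y Trial-averaged firing rates over the test segment.
#' @param fixations A `fixation_table` covering the segment.
#' @param set_a,set_b Disjoint fixation index sets (e.g. high/low spatial
#'   contrast, or nonlinear/linear). Frames of fixations outside both sets
#'   are ignored in the components but still define the means/SDs.
#' @return List of class `corr_split` with `r_pair`, `r_a`, `r_b` (components
#'   over the two sets) and the frame counts.
#' @export
correlation_split <- function(x, y, fixations, set_a, set_b) {
  frames_of <- function(set) unlist(lapply(set, function(i)
    seq.int(fixations$start_frame[i], fixations$end_frame[i] - 1L)))
  fa <- frames_of(set_a); fb <- frames_of(set_b)
  r_a <- partial_correlation(x, y, fa)
  r_b <- partial_correlation(x, y, fb)
  structure(list(r_pair = partial_correlation(x, y, seq_along(x)),
                 r_a = r_a, r_b = r_b,
                 n_frames = length(x), n_a = length(fa), n_b = length(fb)),
            class = "corr_split")
}

#' Pairwise correlation versus receptive-field distance
#'
#' Pearson correlations of trial-averaged rates for all cell pairs, sorted by
#' centre distance and averaged in groups of `group_size` pairs with
#' Student-t 95% confidence intervals.
#'
#' @param rates List of per-cell trial-averaged rate vectors.
#' @param centres Two-column matrix of receptive-field centres (µm).
#' @param group_size Pairs per bin of the binned curve.
#' @return List with `pairs` (data.frame: `i`, `j`, `distance_um`,
#'   `correlation`, `degenerate`) and `curve` (data.frame with bin means and
#'   CIs).
#' @export
correlation_vs_distance <- function(rates, centres, group_size = 20) {
  n <- length(rates)
  stopifnot(nrow(centres) == n)
  pr <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    deg <- stats::sd(rates[[i]]) == 0 || stats::sd(rates[[j]]) == 0
    pr[[length(pr) + 1]] <- data.frame(
      i = i, j = j,
      distance_um = sqrt(sum((centres[i, ] - centres[j, ])^2)),
      correlation = if (deg) NA_real_ else stats::cor(rates[[i]], rates[[j]]),
      degenerate = deg)
  }
  pairs <- do.call(rbind, pr)
  ok <- pairs[!pairs$degenerate, ]
  ok <- ok[order(ok$distance_um), ]
  n_ok <- nrow(ok)
  curve <- NULL
  if (n_ok >= 2) {
    gs <- min(group_size, n_ok)
    bin <- ceiling(seq_len(n_ok) / gs)
    curve <- do.call(rbind, lapply(unique(bin), function(b) {
      r <- ok$correlation[bin == b]; d <- ok$distance_um[bin == b]
      se <- if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else 0
      tq <- if (length(r) > 1) stats::qt(0.975, length(r) - 1) else 0
      data.frame(distance_um = mean(d), correlation = mean(r),
                 ci_lo = mean(r) - tq * se, ci_hi = mean(r) + tq * se,
                 n_pairs = length(r))
    }))
  }
  list(pairs = pairs, curve = curve)
}

#' Stimulus pixel correlation versus distance
#'
#' Pairwise Pearson correlations of the light-intensity time series of
#' randomly selected pixels of a video, as a function of pixel distance, with
#' a binned curve and a linear interpolator for evaluating the stimulus
#' correlation at arbitrary distances.
#'
#' @param video A `stimulus_set` of kind `"video"`.
#' @param frames Frame indices to use (default: all).
#' @param n_pixels Number of randomly selected pixels.
#' @param seed Seed for the pixel sample.
#' @param max_pairs Cap on the number of pixel pairs evaluated.
#' @return List with `pairs` (distance, correlation), `curve`, and
#'   `interp(d)` returning the binned stimulus correlation at distance `d`
#'   (µm).
#' @export
stimulus_pixel_correlation <- function(video, frames = NULL, n_pixels = 300,
                                       seed = 1, max_pairs = 50000) {
  fm <- stimulus_frame_matrix(video)
  if (!is.null(frames)) fm <- fm[frames, , drop = FALSE]
  npx <- ncol(fm)
  sel <- with_seed(derive_seed(seed, 811L), sample(npx, min(n_pixels, npx)))
  sh <- attr(fm, "shape"); pitch <- attr(fm, "pitch")
  rows <- (sel - 1L) %% sh[1] + 1L
  cols <- (sel - 1L) %/% sh[1] + 1L
  co <- pixel_coords(sh, pitch)
  px <- co$x[cols]; py <- co$y[rows]
  keep <- apply(fm[, sel, drop = FALSE], 2, stats::sd) > 0
  sel <- sel[keep]; px <- px[keep]; py <- py[keep]
  cm <- stats::cor(fm[, sel, drop = FALSE])
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  if (nrow(idx) > max_pairs)
    idx <- idx[with_seed(derive_seed(seed, 813L),
                         sample(nrow(idx), max_pairs)), , drop = FALSE]
  d <- sqrt((px[idx[, 1]] - px[idx[, 2]])^2 + (py[idx[, 1]] - py[idx[, 2]])^2)
  r <- cm[idx]
  ord <- order(d)
  d <- d[ord]; r <- r[ord]
  nb <- max(5, min(40, floor(length(d) / 200)))
  bin <- ceiling(seq_along(d) / (length(d) / nb))
  curve <- data.frame(distance_um = as.numeric(tapply(d, bin, mean)),
                      correlation = as.numeric(tapply(r, bin, mean)))
  interp <- function(dd) {
    stats::approx(c(0, curve$distance_um), c(1, curve$correlation),
                  xout = dd, rule = 2)$y
  }
  list(pairs = data.frame(distance_um = d, correlation = r), curve = curve,
       interp = interp)
}

#' Decorrelation of a cell pair relative to the stimulus
#'
#' `(rho_stim - r_resp) / rho_stim` with `rho_stim` the stimulus pixel
#' correlation at the pair's centre distance: 1 when responses are fully
#' decorrelated, 0 when response correlation equals stimulus correlation,
#' negative when responses are more correlated than the stimulus.
#'
#' @param r_resp Response correlation of the pair.
#' @param distance_um Receptive-field centre distance.
#' @param stim_interp Interpolator from [stimulus_pixel_correlation()].
#' @return Scalar decorrelation.
#' @export
decorrelation <- function(r_resp, distance_um, stim_interp) {
  rho <- stim_interp(distance_um)
  (rho - r_resp) / rho
}

#' Direction-selectivity metrics
#'
#' DSI is the magnitude of the normalized complex sum
#' `|sum_theta r_theta exp(i theta)| / sum_theta r_theta` over drift
#' directions, with `r_theta` the trial-averaged spike count; the preferred
#' direction is the argument of the sum. Significance is assessed by a Monte
#' Carlo permutation test shuffling trial responses across directions. The
#' ON-OFF index is `(onset - offset) / (onset + offset)`.
#'
#' @param counts Matrix `trials x directions` of spike counts.
#' @param directions Direction angles in radians (length = columns).
#' @param n_perm Number of permutations.
#' @param seed Permutation seed.
#' @param onset,offset Optional onset/offset spike counts for the ON-OFF
#'   index.
#' @return List of class `ds_metrics` with `dsi`, `preferred_direction`,
#'   `p_perm`, `on_off_index`, `mean_counts`.
#' @export
direction_selectivity <- function(counts, directions, n_perm = 1000, seed = 1,
                                  onset = NULL, offset = NULL) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == length(directions), length(directions) >= 4,
            all(counts >= 0))
  r <- colMeans(counts)
  if (sum(r) == 0) stop("all-zero responses; DSI undefined")
  zsum <- sum(r * exp(1i * directions))
  dsi <- Mod(zsum) / sum(r)
  pref <- Arg(zsum) %% (2 * pi)
  flat <- as.numeric(counts)
  nd <- length(directions); nt <- nrow(counts)
  perm_dsi <- with_seed(derive_seed(seed, 911L), {
    vapply(seq_len(n_perm), function(p) {
      sh <- matrix(sample(flat), nt, nd)
      rs <- colMeans(sh)
      if (sum(rs) == 0) 0 else Mod(sum(rs * exp(1i * directions))) / sum(rs)
    }, numeric(1))
  })
  p_perm <- (1 + sum(perm_dsi >= dsi)) / (n_perm + 1)
  ooi <- if (!is.null(onset) && !is.null(offset)) {
    so <- sum(onset); sf <- sum(offset)
    if (so + sf > 0) (so - sf) / (so + sf) else NA_real_
  } else NA_real_
  structure(list(dsi = dsi, preferred_direction = pref, p_perm = p_perm,
                 on_off_index = ooi, mean_counts = r),
            class = "ds_metrics")
}
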