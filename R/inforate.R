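# Frequency-domain estimation of spike-train signal and noise entropies,
# single-cell and pairwise information rates, and fractional redundancy.
#
# Spike trains binned at 0.4 ms are cut into 0.8 s non-overlapping sections.
# Fourier coefficients of each section are approximately Gaussian across
# sections/trials (central limit theorem), so entropies can be computed
# analytically from their variances: the signal entropy uses the variance
# over sections (averaged over trials), the noise entropy the variance over
# trials (averaged over sections). The information rate is the entropy
# difference summed over frequencies up to a 200 Hz cutoff, divided by the
# section duration.
#
# Two entropy conventions are provided. "printed" sums the cos/sin (and, for
# pairs, eigenvalue) variances inside a single logarithm,
# H = 1/2 log2(2*pi*e*sum(V)); it reproduces the duplicated-cell identity
# I_pair = I_single exactly, but is not additive over independent cells (two
# independent cells with identical statistics would appear fully redundant).
# The default "det" mode uses the full Gaussian entropy,
# H = 1/2 sum_k log2(2*pi*e*lambda_k), which is additive for independent
# cells (fractional redundancy near 0) and near 1 for duplicated signals
# with independent noise. See the methods vignette for the discussion.

#' Section a spike raster and Fourier-transform it
#'
#' @param raster A [spike_raster()] binned at `bin_width` (0.4 ms in the
#'   reference setup) with one row per stimulus repeat.
#' @param section_s Section length in seconds (0.8 in the reference setup).
#' @param cutoff_hz Upper frequency cutoff.
#' @param include_dc Include the DC (f = 0) component. Off by default: the
#'   mean rate is not stimulus-locked modulation.
#' @return Object of class `sectioned_fourier`: arrays `c_cos`, `c_sin` of
#'   dimension `n_freq x n_sections x n_trials`, the frequency grid `f_hz`,
#'   and the sectioning metadata. The trailing part of each trial that does
#'   not fill a section is dropped.
#' @export
section_and_transform <- function(raster, section_s = 0.8, cutoff_hz = 200,
                                  include_dc = FALSE) {
  bw <- raster$bin_width
  stopifnot(is.finite(bw), bw > 0)
  n_bins_sec <- round(section_s / bw)
  n_trials <- nrow(raster$counts)
  n_sections <- floor(ncol(raster$counts) / n_bins_sec)
  if (n_trials < 2 || n_sections < 2)
    stop("need at least 2 trials and 2 full sections")
  df <- 1 / section_s
  k_max <- min(floor(cutoff_hz / df), n_bins_sec %/% 2)
  ks <- if (include_dc) 0:k_max else seq_len(k_max)
  nf <- length(ks)
  c_cos <- array(0, dim = c(nf, n_sections, n_trials))
  c_sin <- array(0, dim = c(nf, n_sections, n_trials))
  for (tr in seq_len(n_trials)) {
    x <- raster$counts[tr, seq_len(n_sections * n_bins_sec)]
    xm <- matrix(x, n_bins_sec, n_sections)
    ft <- stats::mvfft(xm)
    c_cos[, , tr] <- Re(ft[ks + 1L, , drop = FALSE])
    c_sin[, , tr] <- -Im(ft[ks + 1L, , drop = FALSE])
  }
  structure(list(c_cos = c_cos, c_sin = c_sin, f_hz = ks * df,
                 section_s = section_s, bin_width = bw,
                 n_sections = n_sections, n_trials = n_trials),
            class = "sectioned_fourier")
}

# variance over dimension `over` (2 = sections, 3 = trials) averaged over the
# other, per frequency; arr is n_freq x n_sections x n_trials.
#' @keywords internal
var_avg <- function(arr, over) {
  nf <- dim(arr)[1]
  if (over == 2) {
    vapply(seq_len(nf), function(i)
      mean(apply(arr[i, , , drop = FALSE][1, , ], 2, stats::var)),
      numeric(1))
  } else {
    vapply(seq_len(nf), function(i)
      mean(apply(arr[i, , , drop = FALSE][1, , ], 1, stats::var)),
      numeric(1))
  }
}

# 2x2 cos/sin covariance per frequency over sections (signal) or trials
# (noise), averaged over the other dimension.
#' @keywords internal
cov2_avg <- function(sf, which = c("signal", "noise")) {
  which <- match.arg(which)
  nf <- dim(sf$c_cos)[1]
  out <- array(0, dim = c(nf, 2, 2))
  for (i in seq_len(nf)) {
    acc <- matrix(0, 2, 2); n_avg <- 0
    if (which == "signal") {
      for (tr in seq_len(sf$n_trials)) {
        m <- cbind(sf$c_cos[i, , tr], sf$c_sin[i, , tr])
        acc <- acc + stats::cov(m); n_avg <- n_avg + 1
      }
    } else {
      for (se in seq_len(sf$n_sections)) {
        m <- cbind(sf$c_cos[i, se, ], sf$c_sin[i, se, ])
        acc <- acc + stats::cov(m); n_avg <- n_avg + 1
      }
    }
    out[i, , ] <- acc / n_avg
  }
  out
}

#' Signal and noise entropy spectra of a single cell
#'
#' @param sf A [section_and_transform()] result.
#' @param mode `"det"` (full Gaussian entropy from the 2x2 cos/sin
#'   covariance; default) or `"printed"` (summed variances inside one
#'   logarithm). See the module notes above.
#' @return Object of class `entropy_spectrum`: `f_hz`, `h_signal`, `h_noise`
#'   (bits per section per mode; `-Inf` sentinel where a variance vanishes),
#'   the variance components, `section_s` and `mode`.
#' @export
entropy_spectrum <- function(sf, mode = c("det", "printed")) {
  mode <- match.arg(mode)
  v_cos_s <- var_avg(sf$c_cos, 2); v_sin_s <- var_avg(sf$c_sin, 2)
  v_cos_t <- var_avg(sf$c_cos, 3); v_sin_t <- var_avg(sf$c_sin, 3)
  if (mode == "printed") {
    h_signal <- 0.5 * log2(2 * pi * exp(1) * (v_cos_s + v_sin_s))
    h_noise <- 0.5 * log2(2 * pi * exp(1) * (v_cos_t + v_sin_t))
  } else {
    cs <- cov2_avg(sf, "signal"); cn <- cov2_avg(sf, "noise")
    hdet <- function(cc) {
      vapply(seq_len(dim(cc)[1]), function(i) {
        ev <- eigen(cc[i, , ], symmetric = TRUE, only.values = TRUE)$values
        ev <- pmax(ev, 0)
        if (any(ev == 0)) return(-Inf)
        0.5 * sum(log2(2 * pi * exp(1) * ev))
      }, numeric(1))
    }
    h_signal <- hdet(cs); h_noise <- hdet(cn)
  }
  h_signal[!is.finite(h_signal)] <- -Inf
  h_noise[!is.finite(h_noise)] <- -Inf
  structure(list(f_hz = sf$f_hz, h_signal = h_signal, h_noise = h_noise,
                 v_cos_s = v_cos_s, v_sin_s = v_sin_s,
                 v_cos_t = v_cos_t, v_sin_t = v_sin_t,
                 section_s = sf$section_s, mode = mode),
            class = "entropy_spectrum")
}

#' Information rate from an entropy spectrum
#'
#' `I = sum_f (H_signal(f) - H_noise(f)) / T_section` in bits/s. Frequencies
#' where either entropy is at the `-Inf` sentinel are dropped with a warning
#' (the estimator has no noise floor there).
#'
#' @param es An [entropy_spectrum()].
#' @param per_frequency Return the per-frequency contributions instead of the
#'   total.
#' @return Information rate in bits/s (or a vector of per-frequency
#'   contributions in bits/s).
#' @export
information_rate <- function(es, per_frequency = FALSE) {
  contrib <- (es$h_signal - es$h_noise) / es$section_s
  bad <- !is.finite(contrib)
  if (any(bad)) {
    warning(sprintf("%d frequencies with degenerate variances dropped",
                    sum(bad)))
    contrib[bad] <- 0
  }
  if (per_frequency) contrib else sum(contrib)
}

#' Single-cell information rate of a raster
#'
#' Convenience wrapper: [section_and_transform()] then [entropy_spectrum()]
#' then [information_rate()].
#'
#' @inheritParams section_and_transform
#' @inheritParams entropy_spectrum
#' @return Bits/s.
#' @export
cell_information_rate <- function(raster, mode = "det", section_s = 0.8,
                                  cutoff_hz = 200) {
  information_rate(entropy_spectrum(
    section_and_transform(raster, section_s, cutoff_hz), mode = mode))
}

#' Pairwise information rate
#'
#' Gathers the cos/sin coefficients of both cells into a 4x4 covariance
#' matrix per frequency (over sections averaged over trials for the signal;
#' over trials averaged over sections for the noise) and computes the pair
#' entropy from its four eigenvalues: summed inside one logarithm in
#' `"printed"` mode, or as the full Gaussian entropy (sum of eigenvalue
#' logarithms) in `"det"` mode.
#'
#' @param sf_a,sf_b [section_and_transform()] results with matched
#'   sectioning.
#' @param mode `"det"` or `"printed"`.
#' @return List with `i_pair` (bits/s), `h_signal`, `h_noise`, `f_hz`.
#' @export
pair_information <- function(sf_a, sf_b, mode = c("det", "printed")) {
  mode <- match.arg(mode)
  if (!isTRUE(all.equal(sf_a$f_hz, sf_b$f_hz)) ||
      sf_a$n_sections != sf_b$n_sections || sf_a$n_trials != sf_b$n_trials)
    stop("mismatched sectioning between the two cells")
  nf <- length(sf_a$f_hz)
  h_sig <- h_noi <- numeric(nf)
  for (i in seq_len(nf)) {
    acc_s <- matrix(0, 4, 4)
    for (tr in seq_len(sf_a$n_trials)) {
      m <- cbind(sf_a$c_cos[i, , tr], sf_a$c_sin[i, , tr],
                 sf_b$c_cos[i, , tr], sf_b$c_sin[i, , tr])
      acc_s <- acc_s + stats::cov(m)
    }
    acc_n <- matrix(0, 4, 4)
    for (se in seq_len(sf_a$n_sections)) {
      m <- cbind(sf_a$c_cos[i, se, ], sf_a$c_sin[i, se, ],
                 sf_b$c_cos[i, se, ], sf_b$c_sin[i, se, ])
      acc_n <- acc_n + stats::cov(m)
    }
    hp <- function(cc, n_avg) {
      ev <- pmax(eigen(cc / n_avg, symmetric = TRUE,
                       only.values = TRUE)$values, 0)
      if (mode == "printed") {
        s <- sum(ev)
        if (s <= 0) -Inf else 0.5 * log2(2 * pi * exp(1) * s)
      } else {
        if (any(ev <= 0)) -Inf else 0.5 * sum(log2(2 * pi * exp(1) * ev))
      }
    }
    h_sig[i] <- hp(acc_s, sf_a$n_trials)
    h_noi[i] <- hp(acc_n, sf_a$n_sections)
  }
  contrib <- (h_sig - h_noi) / sf_a$section_s
  contrib[!is.finite(contrib)] <- 0
  list(i_pair = sum(contrib), h_signal = h_sig, h_noise = h_noi,
       f_hz = sf_a$f_hz, mode = mode)
}

#' Fractional redundancy of a cell pair
#'
#' `C_ij = (I_i + I_j - I_ij) / min(I_i, I_j)`: 0 when the two cells carry
#' independent information, 1 when one cell adds no information beyond the
#' other; values above 1 or below 0 (synergy) are possible and flagged.
#'
#' @param i_a,i_b Single-cell information rates (bits/s), both positive.
#' @param i_ab Pair information rate (bits/s).
#' @return Scalar `C_ij` with attribute `flag` set to `"synergy"` or
#'   `"super-redundant"` outside `[0, 1]`.
#' @export
fractional_redundancy <- function(i_a, i_b, i_ab) {
  if (min(i_a, i_b) <= 0)
    stop("fractional redundancy undefined for non-positive single-cell information")
  c_frac <- (i_a + i_b - i_ab) / min(i_a, i_b)
  flag <- if (c_frac < 0) "synergy" else if (c_frac > 1) "super-redundant"
          else NULL
  if (!is.null(flag)) attr(c_frac, "flag") <- flag
  c_frac
}

#' Information and redundancy for a pair of rasters
#'
#' @param raster_a,raster_b Fine-binned [spike_raster()]s with matched
#'   geometry.
#' @inheritParams pair_information
#' @inheritParams section_and_transform
#' @return List with `i_a`, `i_b`, `i_pair`, `c_frac`.
#' @export
pair_redundancy <- function(raster_a, raster_b, mode = "det",
                            section_s = 0.8, cutoff_hz = 200) {
  sfa <- section_and_transform(raster_a, section_s, cutoff_hz)
  sfb <- section_and_transform(raster_b, section_s, cutoff_hz)
  i_a <- information_rate(entropy_spectrum(sfa, mode = mode))
  i_b <- information_rate(entropy_spectrum(sfb, mode = mode))
  pi <- pair_information(sfa, sfb, mode = mode)
  list(i_a = i_a, i_b = i_b, i_pair = pi$i_pair,
       c_frac = fractional_redundancy(i_a, i_b, pi$i_pair))
}
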