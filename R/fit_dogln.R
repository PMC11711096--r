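# Maximum-likelihood fitting of the DoG LN model to flashed-grating spike
# counts: R = a * logistic(beta * r_dog + gamma), Poisson likelihood,
# constrained optimization (L-BFGS-B) with the parameter bounds
# sigma_x, sigma_y > 7.5 um, -pi/4 < theta_dog < pi/4, 1 < k_s < 6, a > 0.

#' @keywords internal
dogln_bounds <- function(centre_range = 500) {
  list(lower = c(x0 = -centre_range, y0 = -centre_range, sigma_x = 7.51,
                 sigma_y = 7.51, theta_dog = -pi / 4 + 1e-4, k_s = 1 + 1e-4,
                 w_surr = 0, beta = -1e3, gamma = -50, a = 1e-6),
       upper = c(x0 = centre_range, y0 = centre_range, sigma_x = 400,
                 sigma_y = 400, theta_dog = pi / 4 - 1e-4, k_s = 6 - 1e-4,
                 w_surr = 1 - 1e-4, beta = 1e3, gamma = 50, a = 1e5))
}

# Per-grating sufficient statistics for a flashed battery: number of flashes
# and summed spike count per distinct grating. Each trial enters
# independently, which for a Poisson likelihood reduces to these sums.
#' @keywords internal
aggregate_flash_counts <- function(stim, counts) {
  stopifnot(stim$kind == "flashed_gratings",
            length(counts) == nrow(stim$schedule))
  gid <- stim$schedule$grating_id
  n_g <- tabulate(gid, nbins = nrow(stim$gratings))
  s_g <- as.numeric(rowsum(counts, gid, reorder = TRUE))
  list(gratings = stim$gratings, n = n_g, s = s_g,
       n_spikes = sum(counts), n_flashes = length(counts))
}

#' @keywords internal
dogln_rate <- function(par, gratings, mode) {
  sp <- list(x0 = par[1], y0 = par[2], sigma_x = par[3], sigma_y = par[4],
             theta_dog = par[5], k_s = par[6], w_surr = par[7])
  r <- dog_battery_response(sp, gratings, mode = mode)$response
  pmax(par[10] * logistic(par[8] * r + par[9]), 1e-10)
}

#' @keywords internal
dogln_nll <- function(par, agg, mode) {
  R <- dogln_rate(par, agg$gratings, mode)
  sum(agg$n * R - agg$s * log(R))
}

#' Fit a DoG LN model to flashed-grating responses
#'
#' Minimizes the negative Poisson log-likelihood of per-flash spike counts
#' under `R = a * N(beta * r_dog + gamma)` with a logistic `N`, subject to the
#' standard parameter constraints, using multi-start L-BFGS-B.
#'
#' @param stim A flashed grating battery from [make_grating_battery()].
#' @param counts Spike count per scheduled flash.
#' @param init Optional named list overriding initial values (e.g. `x0`, `y0`
#'   from a receptive-field contour centre).
#' @param n_starts Number of jittered starts; the best final likelihood wins.
#' @param mode Grating amplitude mode (see [dog_grating_response()]).
#' @param seed Seed for start jitter.
#' @return Object of class `dog_ln_fit`: `spatial` ([dog_spatial()]), `beta`,
#'   `gamma`, `a`, `nll`, `converged`, `n_spikes`.
#' @export
fit_dog_ln <- function(stim, counts, init = NULL, n_starts = 3,
                       mode = "exact", seed = 1) {
  agg <- aggregate_flash_counts(stim, counts)
  if (agg$n_spikes < 1) stop("no spikes in the data; cannot fit")
  b <- dogln_bounds()
  mean_count <- agg$n_spikes / agg$n_flashes
  base <- c(x0 = 0, y0 = 0, sigma_x = 50, sigma_y = 50, theta_dog = 0,
            k_s = 2, w_surr = 0.3, beta = 2, gamma = 0,
            a = max(2 * mean_count, 0.5))
  for (nm in names(init)) base[nm] <- init[[nm]]
  parscale <- c(50, 50, 30, 30, 0.3, 1, 0.3, 2, 2, max(base["a"], 1))
  best <- NULL
  for (s in seq_len(n_starts)) {
    p0 <- base
    if (s > 1) {
      jit <- with_seed(derive_seed(seed, 510L, s),
                       stats::rnorm(10, sd = c(30, 30, 15, 15, 0.2, 0.5, 0.2,
                                               1, 1, 0.3 * base[["a"]])))
      p0 <- clamp(base + jit, b$lower + 1e-3, b$upper - 1e-3)
      if (s %% 2 == 0) p0[["beta"]] <- -p0[["beta"]]  # explore OFF polarity
    }
    fit <- tryCatch(
      stats::optim(p0, dogln_nll, agg = agg, mode = mode, method = "L-BFGS-B",
                   lower = b$lower, upper = b$upper,
                   control = list(maxit = 400, parscale = parscale)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("DoG LN optimization failed for all starts")
  p <- best$par
  # canonical orientation: keep sigma_x as the first axis as bounded
  structure(list(
    spatial = dog_spatial(p[["x0"]], p[["y0"]], p[["sigma_x"]], p[["sigma_y"]],
                          p[["theta_dog"]], p[["k_s"]], p[["w_surr"]]),
    beta = p[["beta"]], gamma = p[["gamma"]], a = p[["a"]],
    nll = best$value, converged = best$convergence == 0,
    n_spikes = agg$n_spikes, mode = mode), class = "dog_ln_fit")
}

#' Predicted DoG LN rate for a grating battery
#'
#' @param fit A `dog_ln_fit` (or compatible list).
#' @param stim A flashed grating battery.
#' @param per `"grating"` (one rate per distinct grating) or `"flash"`.
#' @return Predicted spikes per flash.
#' @export
predict_dog_ln <- function(fit, stim, per = c("grating", "flash")) {
  per <- match.arg(per)
  r <- dog_battery_response(fit$spatial, stim$gratings, mode = fit$mode)$response
  R <- fit$a * logistic(fit$beta * r + fit$gamma)
  if (per == "flash") R[stim$schedule$grating_id] else R
}

#' Analytic Poisson negative log-likelihood of given rates
#'
#' Evaluation helper: the NLL (up to the `log(y!)` constant) of observed
#' counts under given per-flash rates.
#'
#' @param rates Predicted mean counts per flash.
#' @param counts Observed counts per flash.
#' @return Scalar NLL.
#' @export
poisson_nll <- function(rates, counts) {
  r <- pmax(rates, 1e-10)
  sum(r - counts * log(r))
}

#' Tuning surface of flashed-grating responses
#'
#' Summarizes per-flash spike counts as the mean response per
#' frequency-orientation pair, averaged over trials and spatial phases.
#' This is a visualization/summary device; model fitting always uses the
#' raw per-flash counts.
#'
#' @param stim A flashed grating battery.
#' @param counts Spike count per scheduled flash.
#' @return Data frame with `f`, `theta`, `mean_count`, `n_flashes`.
#' @export
tuning_surface <- function(stim, counts) {
  stopifnot(stim$kind == "flashed_gratings",
            length(counts) == nrow(stim$schedule))
  g <- stim$gratings[stim$schedule$grating_id, ]
  key <- interaction(g$f, g$theta, drop = TRUE)
  agg <- data.frame(f = tapply(g$f, key, `[`, 1),
                    theta = tapply(g$theta, key, `[`, 1),
                    mean_count = as.numeric(tapply(counts, key, mean)),
                    n_flashes = as.numeric(table(key)))
  agg[order(agg$f, agg$theta), ]
}
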