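# Subunit grid model: R_SG = G( sum_s w_s * N(beta * r_s + gamma) ) with
# identical circular DoG subunits on a hexagonal candidate grid, non-negative
# weights, logistic subunit nonlinearity N and Naka-Rushton output G.
# Fitting minimizes
#   -(1/N_sp) ln L + lambda * sum_s w_s * sum_{i != s} w_i / d_si^2
# by ADAM with projected gradients, followed by pruning of small/outlying
# weights, an output-nonlinearity refit, and BIC model selection across a
# ladder of regularization strengths.

#' Hexagonal candidate subunit grid
#'
#' Places `n_sites` candidate subunit locations on a hexagonal lattice of the
#' given spacing, keeping the sites closest to the centre.
#'
#' @param centre Receptive-field centre `c(x, y)` in µm (typically from a
#'   fitted DoG model or a receptive-field contour).
#' @param n_sites Number of candidate sites (1200 in the reference setup).
#' @param spacing Lattice spacing in µm (16 in the reference setup).
#' @return Two-column matrix of site positions (µm).
#' @export
subunit_grid <- function(centre = c(0, 0), n_sites = 1200, spacing = 16) {
  rings <- ceiling((-3 + sqrt(9 + 12 * (n_sites - 1))) / 6) + 1
  pts <- hex_mosaic(rings, spacing, centre = centre)
  d2 <- (pts[, 1] - centre[1])^2 + (pts[, 2] - centre[2])^2
  pts[order(d2)[seq_len(min(n_sites, nrow(pts)))], , drop = FALSE]
}

#' Subunit grid model parameters
#'
#' @param grid Two-column matrix of subunit centres (µm).
#' @param w Non-negative subunit weights.
#' @param sigma Shared subunit centre SD (µm).
#' @param k_s,w_surr Shared subunit surround scale and strength.
#' @param beta,gamma Subunit logistic nonlinearity parameters.
#' @param out Naka-Rushton output parameters `list(a, b, n, k)` (`b` only in
#'   the flashed variant).
#' @param mode Grating amplitude mode.
#' @return Object of class `sg_params`.
#' @export
sg_params <- function(grid, w, sigma = 12, k_s = 2, w_surr = 0.2,
                      beta = 2, gamma = 0,
                      out = list(a = 1, b = 0.01, n = 2, k = 1),
                      mode = "exact") {
  grid <- as.matrix(grid)
  stopifnot(ncol(grid) == 2, length(w) == nrow(grid), all(w >= 0),
            all(unlist(out) >= 0))
  structure(list(grid = grid, w = w, sigma = sigma, k_s = k_s,
                 w_surr = w_surr, beta = beta, gamma = gamma, out = out,
                 mode = mode), class = "sg_params")
}

# Subunit grating activations r_s for a grating table: (gratings x subunits).
#' @keywords internal
sg_activations <- function(params, gratings) {
  c0 <- amp_const(params$mode)
  f <- gratings$f
  A <- exp(-c0 * params$sigma^2 * f^2) -
    params$w_surr * exp(-c0 * (params$k_s * params$sigma)^2 * f^2)
  A * sg_cos_theta(params$grid, gratings)
}

#' Subunit grid model prediction
#'
#' Predicted response to a grating battery (analytic subunit activations) or
#' to a stack of images (pixel-space subunit filters).
#'
#' @param params An [sg_params()].
#' @param stim A grating battery `stimulus_set`, a grating table
#'   (data.frame with `f`, `theta`, `phi`), or a list of contrast images.
#' @param pixel_pitch Pixel pitch (µm), required for image input.
#' @return Predicted rate per grating / image (non-negative).
#' @export
sg_predict <- function(params, stim, pixel_pitch = NULL) {
  if (is.data.frame(stim)) {
    act <- sg_activations(params, stim)
  } else if (inherits(stim, "stimulus_set") &&
             stim$kind %in% c("flashed_gratings", "flicker_gratings")) {
    act <- sg_activations(params, stim$gratings)
  } else if (is.list(stim)) {
    if (is.null(pixel_pitch)) stop("pixel_pitch required for image input")
    sh <- dim(stim[[1]])
    enc <- list(centres = params$grid, sigma = params$sigma, k_s = params$k_s,
                w_surr = params$w_surr)
    filt <- sg_filter_matrix(enc, sh, pixel_pitch)
    fm <- t(vapply(stim, as.numeric, numeric(prod(sh))))
    act <- fm %*% filt
  } else stop("unsupported stimulus for sg_predict")
  pooled <- as.numeric(logistic(params$beta * act + params$gamma) %*% params$w)
  naka_rushton(pooled, params$out)
}

# Full Poisson log-likelihood (with the log y! term) of an sg model on
# aggregated flashed data.
#' @keywords internal
sg_loglik <- function(params, agg) {
  R <- pmax(sg_predict(params, agg$gratings), 1e-10)
  sum(agg$s * log(R) - agg$n * R) - agg$lfact
}

# ---- packing and projection -------------------------------------------------

#' @keywords internal
sg_pack <- function(params) {
  c(params$w, params$sigma, params$k_s, params$w_surr, params$beta,
    params$gamma, params$out$a, params$out$b, params$out$n, params$out$k)
}

#' @keywords internal
sg_unpack <- function(theta, params) {
  ns <- nrow(params$grid)
  params$w <- theta[seq_len(ns)]
  params$sigma <- theta[ns + 1]; params$k_s <- theta[ns + 2]
  params$w_surr <- theta[ns + 3]; params$beta <- theta[ns + 4]
  params$gamma <- theta[ns + 5]
  params$out <- list(a = theta[ns + 6], b = theta[ns + 7], n = theta[ns + 8],
                     k = theta[ns + 9])
  params
}

# Projection enforcing all constraints exactly after each optimizer step.
#' @keywords internal
sg_project <- function(theta, ns, with_baseline = TRUE, fix_k = TRUE) {
  theta[seq_len(ns)] <- pmax(theta[seq_len(ns)], 0)
  theta[ns + 1] <- clamp(theta[ns + 1], 7.51, 200)        # sigma
  theta[ns + 2] <- clamp(theta[ns + 2], 1 + 1e-3, 6 - 1e-3)  # k_s
  theta[ns + 3] <- clamp(theta[ns + 3], 0, 1 - 1e-3)      # w_surr
  theta[ns + 5] <- clamp(theta[ns + 5], -50, 50)          # gamma
  theta[ns + 6] <- max(theta[ns + 6], 1e-6)               # out a
  theta[ns + 7] <- if (with_baseline) max(theta[ns + 7], 0) else 0
  theta[ns + 8] <- clamp(theta[ns + 8], 0.5, 8)           # out n
  # the half-saturation k is degenerate with a global weight rescaling (and
  # the density penalty is not); pinning k = 1 during the stochastic phase
  # stops the optimizer from evading the penalty by shrinking all weights
  theta[ns + 9] <- if (fix_k) 1 else max(theta[ns + 9], 1e-3)
  theta
}

# ---- cost and gradient on a batch of flashes --------------------------------

# Batch negative log-likelihood gradient (d cost / d theta) at flash level.
# agg-level precomputations: cosT (gratings x subunits), f (per grating).
#' @keywords internal
sg_batch_grad <- function(theta, ns, gid, y, cosT, f, c0, scale, dinv2,
                          lambda, n_rep = 1) {
  w <- theta[seq_len(ns)]
  sigma <- theta[ns + 1]; k_s <- theta[ns + 2]; w_surr <- theta[ns + 3]
  beta <- theta[ns + 4]; gamma <- theta[ns + 5]
  a <- theta[ns + 6]; b <- theta[ns + 7]; n <- theta[ns + 8]; k <- theta[ns + 9]
  fb <- f[gid]
  e1 <- exp(-c0 * sigma^2 * fb^2)
  e2 <- exp(-c0 * (k_s * sigma)^2 * fb^2)
  A <- e1 - w_surr * e2
  cT <- cosT[gid, , drop = FALSE]
  r <- A * cT
  z <- beta * r + gamma
  Nz <- logistic(z)
  u <- pmax(as.numeric(Nz %*% w), 0)
  un <- u^n; kn <- k^n; den <- un + kn
  G <- pmax(a * un / den + b, 1e-10)
  nll <- sum(n_rep * G - y * log(G)) * scale
  dG <- (n_rep - y / G) * scale
  dGdu <- ifelse(u > 0, a * n * u^(n - 1) * kn / den^2, 0)
  gu <- dG * dGdu
  P <- Nz * (1 - Nz)
  M <- (gu %o% w) * P                          # batch x subunits
  gw <- as.numeric(crossprod(Nz, gu))
  gbeta <- sum(M * r)
  ggamma <- sum(M)
  dA_dsigma <- -2 * c0 * sigma * fb^2 * e1 +
    w_surr * 2 * c0 * k_s^2 * sigma * fb^2 * e2
  dA_dk <- w_surr * 2 * c0 * k_s * sigma^2 * fb^2 * e2
  dA_dws <- -e2
  Mb <- beta * M * cT
  gsigma <- sum(Mb * dA_dsigma)
  gk_s <- sum(Mb * dA_dk)
  gw_surr <- sum(Mb * dA_dws)
  ga <- sum(dG * un / den)
  gb <- sum(dG)
  gn <- sum(dG * ifelse(u > 0, a * kn * un * (log(u) - log(k)) / den^2, 0))
  gk <- sum(dG * (-a * n * un * k^(n - 1)) / den^2)
  grad <- c(gw, gsigma, gk_s, gw_surr, gbeta, ggamma, ga, gb, gn, gk)
  if (lambda > 0) {
    pen_grad <- 2 * lambda * as.numeric(dinv2 %*% w)
    grad[seq_len(ns)] <- grad[seq_len(ns)] + pen_grad
    nll <- nll + lambda * sum(w * (dinv2 %*% w))
  }
  list(grad = grad, cost = nll)
}

# Deterministic full-batch refinement of the shared parameters (sigma, k_s,
# w_surr, beta, gamma, Naka-Rushton) plus a global weight scale, holding the
# relative weight profile fixed. The stochastic ADAM phase learns the weight
# layout quickly but moves the shared parameters only slowly against
# minibatch noise; this polish runs L-BFGS-B on the per-grating sufficient
# statistics with the analytic gradient to finish that subspace.
#' @keywords internal
sg_polish_shared <- function(params, agg, cosT, dinv2, lambda) {
  ns <- nrow(params$grid)
  w_base <- params$w
  gid <- seq_len(nrow(agg$gratings))
  fn_gr <- function(par) {
    th <- c(w_base * exp(par[1]), par[-1])
    g <- sg_batch_grad(th, ns, gid, agg$s, cosT, agg$gratings$f,
                       amp_const(params$mode), 1 / agg$n_spikes, dinv2,
                       lambda, n_rep = agg$n)
    grad_scale <- sum(g$grad[seq_len(ns)] * w_base * exp(par[1]))
    list(value = g$cost, grad = c(grad_scale, g$grad[ns + 1:9]))
  }
  lower <- c(-5, 7.51, 1 + 1e-3, 0, -1e3, -50, 1e-6, 0, 0.5, 1)
  upper <- c(5, 200, 6 - 1e-3, 1 - 1e-3, 1e3, 50, 1e6, 1e6, 8, 1)
  p0 <- clamp(c(0, params$sigma, params$k_s, params$w_surr, params$beta,
                params$gamma, params$out$a, params$out$b %||% 0,
                params$out$n, params$out$k), lower, upper)
  op <- tryCatch(
    stats::optim(p0, function(p) fn_gr(p)$value, function(p) fn_gr(p)$grad,
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 100)),
    error = function(e) NULL)
  if (is.null(op) || op$value > fn_gr(p0)$value) return(params)
  p <- op$par
  params$w <- w_base * exp(p[1])
  params$sigma <- p[2]; params$k_s <- p[3]; params$w_surr <- p[4]
  params$beta <- p[5]; params$gamma <- p[6]
  params$out <- list(a = p[7], b = p[8], n = p[9], k = p[10])
  params
}

#' Subunit grid fit configuration
#'
#' @param lambda Density-regularizer strength.
#' @param eta_max Peak ADAM learning rate (Gaussian schedule with mean
#'   `n_epochs / 2` and SD `n_epochs / 5`).
#' @param beta1,beta2,eps ADAM moment parameters.
#' @param batch Batch size in flashes.
#' @param n_epochs Number of passes over the data; `NULL` selects the
#'   reference schedule `4e5 / N_trials` (N_trials = number of flashes).
#' @param seed Seed controlling batching and weight-initialization jitter.
#' @param n_sites,spacing Candidate grid layout.
#' @param sigma_init Initial subunit SD (µm).
#' @param rf_sigma_init SD of the Gaussian used to seed the weights from the
#'   receptive-field centre (µm).
#' @param beta_init,gamma_init Initial subunit nonlinearity parameters.
#' @param polish Run a deterministic full-batch refinement of the shared
#'   parameters (and global weight scale) after the stochastic phase.
#' @return List of class `sg_config`.
#' @export
sg_config <- function(lambda = 1e-5, eta_max = 0.005, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-6, batch = 64, n_epochs = NULL,
                      seed = 1, n_sites = 1200, spacing = 16,
                      sigma_init = 12, rf_sigma_init = 60,
                      beta_init = 2, gamma_init = 0, polish = TRUE) {
  structure(list(lambda = lambda, eta_max = eta_max, beta1 = beta1,
                 beta2 = beta2, eps = eps, batch = batch, n_epochs = n_epochs,
                 seed = seed, n_sites = n_sites, spacing = spacing,
                 sigma_init = sigma_init, rf_sigma_init = rf_sigma_init,
                 beta_init = beta_init, gamma_init = gamma_init,
                 polish = polish),
            class = "sg_config")
}

#' Fit a subunit grid model to flashed-grating responses
#'
#' ADAM stochastic optimization of the regularized negative Poisson
#' log-likelihood, with a Gaussian learning-rate schedule, per-epoch trial
#' shuffling, and projection of all constraints after every step.
#'
#' @param stim A flashed grating battery.
#' @param counts Spike count per scheduled flash.
#' @param centre_init Grid centre `c(x, y)` in µm (typically the fitted DoG
#'   centre).
#' @param config An [sg_config()].
#' @param mode Grating amplitude mode.
#' @return Object of class `sg_fit`: `params` ([sg_params()]), `cost_trace`
#'   (per-epoch running cost), `loglik` (full-data Poisson log-likelihood),
#'   `lambda`, `n_spikes`.
#' @export
fit_sg <- function(stim, counts, centre_init = c(0, 0), config = sg_config(),
                   mode = "exact") {
  agg <- aggregate_flash_counts(stim, counts)
  agg$lfact <- sum(lgamma(counts + 1))
  if (agg$n_spikes < 1) stop("no spikes in the data; cannot fit")
  grid <- subunit_grid(centre_init, config$n_sites, config$spacing)
  ns <- nrow(grid)
  # penalty distances in mm: with the pinned weight scale (see sg_project)
  # this gives the reference lambda ladder its full dynamic range, from a
  # negligible penalty to one that strongly consolidates the subunit layout
  d2 <- as.matrix(stats::dist(grid / 1000))^2
  dinv2 <- 1 / d2; diag(dinv2) <- 0
  # weight init: centre-Gaussian profile at the grid sites, small scale,
  # with seed-controlled jitter
  d2c <- (grid[, 1] - centre_init[1])^2 + (grid[, 2] - centre_init[2])^2
  w0 <- exp(-d2c / (2 * config$rf_sigma_init^2))
  w0 <- w0 * with_seed(derive_seed(config$seed, 601L),
                       stats::runif(ns, 0.5, 1.5))
  # scale so the initial pooled drive sits near the (pinned) half-saturation
  w0 <- w0 / sum(w0) * 2
  mean_count <- agg$n_spikes / agg$n_flashes
  params <- sg_params(grid, w0, sigma = config$sigma_init, k_s = 2,
                      w_surr = 0.2, beta = config$beta_init,
                      gamma = config$gamma_init,
                      out = list(a = max(2 * mean_count, 0.5), b = 0.01,
                                 n = 2, k = 1),
                      mode = mode)
  cosT <- sg_cos_theta(grid, agg$gratings)
  f <- agg$gratings$f
  c0 <- amp_const(mode)
  gid_all <- stim$schedule$grating_id
  y_all <- counts
  nfl <- length(y_all)
  n_epochs <- config$n_epochs
  if (is.null(n_epochs)) n_epochs <- max(1, round(4e5 / nfl))
  theta <- sg_pack(params)
  m <- v <- numeric(length(theta))
  scale <- nfl / agg$n_spikes / config$batch * config$batch  # 1/N_sp per-flash
  step <- 0
  cost_trace <- numeric(n_epochs)
  for (ep in seq_len(n_epochs)) {
    ord <- with_seed(derive_seed(config$seed, 603L, ep), sample(nfl))
    eta <- config$eta_max *
      exp(-(ep - n_epochs / 2)^2 / (2 * (n_epochs / 5)^2))
    starts <- seq(1, nfl, by = config$batch)
    ep_cost <- 0
    for (b0 in starts) {
      idx <- ord[b0:min(b0 + config$batch - 1, nfl)]
      step <- step + 1
      # per-flash cost scaled by 1/N_sp; batch mean times total flash count
      sc <- nfl / (agg$n_spikes * length(idx))
      g <- sg_batch_grad(theta, ns, gid_all[idx], y_all[idx], cosT, f, c0,
                         sc, dinv2, config$lambda)
      ep_cost <- ep_cost + g$cost * length(idx) / nfl
      m <- config$beta1 * m + (1 - config$beta1) * g$grad
      v <- config$beta2 * v + (1 - config$beta2) * g$grad^2
      mhat <- m / (1 - config$beta1^step)
      vhat <- v / (1 - config$beta2^step)
      theta <- theta - eta * mhat / (sqrt(vhat) + config$eps)
      theta <- sg_project(theta, ns)
    }
    cost_trace[ep] <- ep_cost
    if (!all(is.finite(theta))) stop("subunit grid optimization diverged")
  }
  params <- sg_unpack(theta, params)
  if (isTRUE(config$polish))
    params <- sg_polish_shared(params, agg, cosT, dinv2, config$lambda)
  structure(list(params = params, cost_trace = cost_trace,
                 loglik = sg_loglik(params, agg), lambda = config$lambda,
                 n_spikes = agg$n_spikes, n_data = nfl,
                 centre_init = centre_init, config = config),
            class = "sg_fit")
}

#' Prune subunit weights and refit the output nonlinearity
#'
#' Sets to zero every weight smaller than 5% of the maximum weight, fits a 2-D
#' Gaussian to the weight-summed subunit receptive fields and zeroes weights
#' of subunits lying more than 2.5 sigma outside that Gaussian, then refits
#' the output-nonlinearity parameters together with a global weight scaling
#' factor by maximum likelihood on the training data.
#'
#' @param fit An `sg_fit`.
#' @param stim,counts The training battery and counts used for the refit.
#' @param weight_frac Small-weight threshold as a fraction of the maximum.
#' @param maha_cut Mahalanobis cutoff (in SDs of the fitted Gaussian).
#' @return The pruned and refitted `sg_fit`; `params$w` has zeros for pruned
#'   subunits. If pruning removes all subunits the model is flagged
#'   ineligible (`eligible = FALSE`).
#' @export
prune_and_refit <- function(fit, stim, counts, weight_frac = 0.05,
                            maha_cut = 2.5) {
  params <- fit$params
  w <- params$w
  if (!any(w > 0)) stop("no non-zero weight to prune")
  w[w < weight_frac * max(w)] <- 0
  if (any(w > 0)) {
    # Gaussian fitted to the weighted sum of subunit receptive fields:
    # weighted mean/covariance of the centres, broadened by the subunit SD
    act <- w > 0
    mu <- colSums(params$grid[act, , drop = FALSE] * w[act]) / sum(w[act])
    dc <- sweep(params$grid[act, , drop = FALSE], 2, mu)
    cov <- crossprod(dc * w[act], dc) / sum(w[act]) +
      diag(params$sigma^2, 2)
    maha <- sqrt(stats::mahalanobis(params$grid, mu, cov))
    w[maha > maha_cut] <- 0
  }
  params$w <- w
  if (!any(w > 0)) {
    fit$params <- params
    fit$eligible <- FALSE
    return(fit)
  }
  agg <- aggregate_flash_counts(stim, counts)
  agg$lfact <- sum(lgamma(counts + 1))
  pooled0 <- as.numeric(
    logistic(params$beta * sg_activations(params, agg$gratings) +
               params$gamma) %*% params$w)
  with_baseline <- !is.null(params$out$b)
  obj <- function(th) {
    sc <- exp(th[1])
    out <- list(a = exp(th[2]), b = if (with_baseline) exp(th[3]) else 0,
                n = clamp(exp(th[4]), 0.5, 8), k = exp(th[5]))
    R <- pmax(naka_rushton(sc * pooled0, out), 1e-10)
    sum(agg$n * R - agg$s * log(R))
  }
  th0 <- c(0, log(max(params$out$a, 1e-4)),
           log(max(if (with_baseline) params$out$b else 1, 1e-4)),
           log(params$out$n), log(params$out$k))
  op <- stats::optim(th0, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-10))
  params$w <- params$w * exp(op$par[1])
  params$out <- list(a = exp(op$par[2]),
                     b = if (with_baseline) exp(op$par[3]) else 0,
                     n = clamp(exp(op$par[4]), 0.5, 8), k = exp(op$par[5]))
  # absorb the weight rescale into the Naka-Rushton half-saturation instead of
  # the weights so subunit nonlinearity inputs stay on the fitted scale:
  # G(sc*x; k) = G(x; k/sc) for the rescaled pooled signal
  fit$params <- params
  fit$loglik <- sg_loglik(params, agg)
  fit$eligible <- TRUE
  fit
}

#' Full refit of a pruned subunit grid model on its support
#'
#' Deterministic L-BFGS-B maximum-likelihood refinement of all model
#' parameters (individual weights, subunit geometry, nonlinearities) on the
#' support retained by pruning. The stochastic phase is good at discovering
#' the weight support but converges slowly in the shared-parameter subspace;
#' once the support is small, the regularized likelihood can be optimized to
#' convergence directly, which in particular sharpens the subunit
#' nonlinearity. Weights that fall below 5% of the maximum during the refit
#' are zeroed and the model is briefly re-polished.
#'
#' @param fit A pruned `sg_fit` (from [prune_and_refit()]).
#' @param stim,counts Training battery and per-flash counts.
#' @param maxit L-BFGS-B iteration cap.
#' @return The refined `sg_fit` with updated `params` and `loglik`.
#' @export
sg_refine <- function(fit, stim, counts, maxit = 500) {
  p <- fit$params
  agg <- aggregate_flash_counts(stim, counts)
  agg$lfact <- sum(lgamma(counts + 1))
  refit_once <- function(p, act, maxit) {
    ns <- length(act)
    cosT <- sg_cos_theta(p$grid[act, , drop = FALSE], agg$gratings)
    dinv2 <- 1 / as.matrix(stats::dist(p$grid[act, , drop = FALSE] / 1000))^2
    diag(dinv2) <- 0
    gid <- seq_len(nrow(agg$gratings))
    c0 <- amp_const(p$mode)
    fn_gr <- function(th)
      sg_batch_grad(th, ns, gid, agg$s, cosT, agg$gratings$f, c0,
                    1 / agg$n_spikes, dinv2, fit$lambda, n_rep = agg$n)
    th0 <- c(p$w[act], p$sigma, p$k_s, p$w_surr, p$beta, p$gamma,
             p$out$a, p$out$b %||% 0, p$out$n, 1)
    lower <- c(rep(0, ns), 7.51, 1 + 1e-3, 0, -1e3, -50, 1e-6, 0, 0.5, 1)
    upper <- c(rep(Inf, ns), 200, 6 - 1e-3, 1 - 1e-3, 1e3, 50, 1e6, 1e6, 8, 1)
    op <- tryCatch(
      stats::optim(clamp(th0, lower, upper),
                   function(t) fn_gr(t)$cost, function(t) fn_gr(t)$grad,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = maxit)),
      error = function(e) NULL)
    if (is.null(op)) return(p)
    th <- op$par
    w_new <- numeric(nrow(p$grid))
    w_new[act] <- pmax(th[seq_len(ns)], 0)
    p$w <- w_new
    p$sigma <- th[ns + 1]; p$k_s <- th[ns + 2]; p$w_surr <- th[ns + 3]
    p$beta <- th[ns + 4]; p$gamma <- th[ns + 5]
    p$out <- list(a = th[ns + 6],
                  b = if (is.null(p$out$b)) NULL else th[ns + 7],
                  n = th[ns + 8], k = th[ns + 9])
    p
  }
  act <- which(p$w > 0)
  if (!length(act)) return(fit)
  p <- refit_once(p, act, maxit)
  keep <- which(p$w >= 0.05 * max(p$w))
  if (length(keep) < sum(p$w > 0)) {
    p$w[setdiff(which(p$w > 0), keep)] <- 0
    p <- refit_once(p, keep, 200)
  }
  fit$params <- p
  fit$loglik <- sg_loglik(p, agg)
  fit$eligible <- any(p$w > 0)
  fit
}

#' Receptive-field coverage of a subunit grid model
#'
#' Ratio `A / B` with `A = 4 * sigma` (subunit diameter) and `B` the average
#' nearest-neighbour distance between subunits with non-zero weights,
#' weighted by each pair's average subunit weight. Undefined (error) for
#' fewer than three non-zero weights.
#'
#' @param params An [sg_params()].
#' @return Scalar coverage.
#' @export
sg_coverage <- function(params) {
  act <- which(params$w > 0)
  if (length(act) < 3)
    stop("coverage undefined for fewer than three non-zero subunits")
  pts <- params$grid[act, , drop = FALSE]
  w <- params$w[act]
  dm <- as.matrix(stats::dist(pts)); diag(dm) <- Inf
  nn <- apply(dm, 1, which.min)
  nnd <- dm[cbind(seq_along(nn), nn)]
  pw <- (w + w[nn]) / 2
  B <- sum(nnd * pw) / sum(pw)
  (4 * params$sigma) / B
}

#' Subunit nonlinearity asymmetry
#'
#' The subunit nonlinearity is offset so that zero input maps to zero output
#' and scaled so its maximum over the input range `[-1, 1]` is one; the
#' asymmetry is `(1 - M) / (1 + M)` with `M` the absolute value of the
#' minimum of the normalized nonlinearity over `[-1, 1]`. 0 indicates an
#' odd-symmetric (linear-like) nonlinearity, 1 full rectification.
#'
#' @param params An [sg_params()] (uses `beta`, `gamma`), or a function of one
#'   argument.
#' @param n_grid Evaluation grid size on `[-1, 1]`.
#' @return Asymmetry in `[-1, 1]`.
#' @export
nonlinearity_asymmetry <- function(params, n_grid = 2001) {
  x <- seq(-1, 1, length.out = n_grid)
  fx <- if (is.function(params)) params(x)
        else logistic(params$beta * x + params$gamma)
  f0 <- if (is.function(params)) params(0) else logistic(params$gamma)
  fx <- fx - f0
  mx <- max(fx)
  if (mx <= 0) return(0)
  fx <- fx / mx
  M <- abs(min(fx))
  (1 - M) / (1 + M)
}

#' Bayesian information criterion of a subunit grid fit
#'
#' `BIC = N_sub * ln(N_data) - 2 * ln(L)` with `N_sub` the number of subunits
#' with non-zero weight and `N_data` the number of grating-response pairs.
#'
#' @param n_sub Number of non-zero-weight subunits.
#' @param n_data Number of grating-response pairs used in the fit.
#' @param loglik Poisson log-likelihood of the fitted model.
#' @return Scalar BIC.
#' @export
sg_bic <- function(n_sub, n_data, loglik) n_sub * log(n_data) - 2 * loglik

#' Select the best subunit grid model across a regularization ladder
#'
#' A candidate is eligible if it retains at least `min_subunits` subunits and
#' has coverage below `max_coverage`. Among eligible candidates the one with
#' minimal BIC wins; exact ties go to the smaller lambda. With no eligible
#' candidate an "excluded" status is returned.
#'
#' @param fits List of (pruned) `sg_fit` objects.
#' @param min_subunits,max_coverage Eligibility thresholds (3 and 3 in the
#'   reference setup).
#' @return List with `status` (`"selected"` or `"excluded"`), `fit` (the
#'   winning `sg_fit` or `NULL`) and a `table` of per-candidate diagnostics.
#' @export
select_model <- function(fits, min_subunits = 3, max_coverage = 3) {
  tab <- do.call(rbind, lapply(fits, function(f) {
    ns <- sum(f$params$w > 0)
    cov <- if (ns >= min_subunits) tryCatch(sg_coverage(f$params),
                                            error = function(e) NA_real_)
           else NA_real_
    data.frame(lambda = f$lambda, n_sub = ns, coverage = cov,
               loglik = f$loglik,
               bic = sg_bic(ns, f$n_data, f$loglik),
               eligible = isTRUE(f$eligible %||% TRUE) && ns >= min_subunits &&
                 is.finite(cov) && cov < max_coverage)
  }))
  if (!any(tab$eligible))
    return(list(status = "excluded", fit = NULL, table = tab))
  el <- which(tab$eligible)
  ord <- el[order(tab$bic[el], tab$lambda[el])]
  list(status = "selected", fit = fits[[ord[1]]], table = tab)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit, prune and select over a lambda ladder
#'
#' Convenience wrapper running [fit_sg()] and [prune_and_refit()] for each
#' regularization strength and applying [select_model()].
#'
#' @inheritParams fit_sg
#' @param lambdas Regularization ladder (default: six values log-spaced from
#'   1e-6 to 5e-4).
#' @param refine Run the deterministic support refit ([sg_refine()]) after
#'   pruning on each rung.
#' @return The [select_model()] result, with the per-lambda fits attached as
#'   `fits`.
#' @export
fit_sg_ladder <- function(stim, counts, centre_init = c(0, 0),
                          lambdas = 10^seq(log10(1e-6), log10(5e-4),
                                           length.out = 6),
                          config = sg_config(), mode = "exact",
                          refine = TRUE) {
  fits <- lapply(lambdas, function(l) {
    cfg <- config; cfg$lambda <- l
    f <- fit_sg(stim, counts, centre_init, cfg, mode = mode)
    f <- prune_and_refit(f, stim, counts)
    if (refine && isTRUE(f$eligible)) f <- sg_refine(f, stim, counts)
    f
  })
  sel <- select_model(fits)
  sel$fits <- fits
  sel
}
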