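# Spatiotemporal model variants fitted to flickering gratings: a raised-cosine
# temporal basis, the spatiotemporal DoG LN model
#   R = a * N(r_C' k_Ct + r_S' k_St + b)
# and the spatiotemporal subunit grid model
#   R = G( sum_s w_s * N(r_C' k_Ct + r_S' k_St + gamma) )
# where r_C (r_S) hold the centre (surround) Gaussian activations over the
# 500 ms of stimulus history ending at the start of the response bin.

#' Temporal basis for 500 ms filters
#'
#' Ten basis vectors over the lag window: two single-frame boxcars for the two
#' frames immediately before the response bin, and eight raised cosines with
#' peaks spaced from 0 to 250 ms before the bin.
#'
#' @param frame_rate Stimulus frame rate (Hz).
#' @param window_s Lag window duration (s).
#' @param n_cos Number of raised cosines.
#' @param peak_range_s Range of raised-cosine peak times (s).
#' @return Matrix `n_lags x (2 + n_cos)`; lag `l` corresponds to the frame
#'   `l` steps before the response bin. Columns 1-2 are the boxcars.
#' @export
build_temporal_basis <- function(frame_rate, window_s = 0.5, n_cos = 8,
                                 peak_range_s = c(0, 0.25)) {
  n_lags <- round(window_s * frame_rate)
  stopifnot(n_lags >= 3)
  t_lag <- (seq_len(n_lags) - 1) / frame_rate
  B <- matrix(0, n_lags, 2 + n_cos)
  B[1, 1] <- 1
  B[2, 2] <- 1
  mus <- seq(peak_range_s[1], peak_range_s[2], length.out = n_cos)
  half_width <- 2 * diff(mus[1:2])
  for (j in seq_len(n_cos)) {
    d <- t_lag - mus[j]
    inside <- abs(d) < half_width
    B[inside, 2 + j] <- 0.5 * (1 + cos(pi * d[inside] / half_width))
  }
  B
}

# Centre and surround grating activations per frame for a flicker sequence.
# Returns list(actC, actS) vectors over frames; actS includes the w_surr
# scale. Spatial parameters as in the DoG model; for circular subunits pass
# sigma_x = sigma_y.
#' @keywords internal
st_frame_activations <- function(sp, gr, gid, mode) {
  c0 <- amp_const(mode)
  f <- gr$f[gid]; th <- gr$theta[gid]; phi <- gr$phi[gid]
  sig2 <- sp$sigma_y^2 * sin(th + sp$theta_dog)^2 +
    sp$sigma_x^2 * cos(th + sp$theta_dog)^2
  E1 <- exp(-c0 * sig2 * f^2)
  E2 <- exp(-c0 * sp$k_s^2 * sig2 * f^2)
  Theta <- 2 * pi * f * (sp$x0 * cos(th) + sp$y0 * sin(th)) + phi - pi / 2
  cth <- cos(Theta)
  list(actC = E1 * cth, actS = sp$w_surr * E2 * cth,
       E1 = E1, E2 = E2, cth = cth, sth = sin(Theta), f = f, th = th,
       sig2 = sig2)
}

# Lagged design matrix: X[t, j] = sum_l B[l, j] * act[t - l]; rows with
# incomplete history are zero-padded and flagged.
#' @keywords internal
lag_design <- function(act, B) {
  n <- length(act); L <- nrow(B)
  E <- matrix(0, n, L)
  for (l in seq_len(L)) E[(l + 1):n, l] <- act[seq_len(n - l)]
  E %*% B
}

# Objective/gradient factory for the spatiotemporal DoG LN likelihood.
#' @keywords internal
st_dog_objective <- function(stim, counts, init = NULL, mode = "exact") {
  stopifnot(stim$kind == "flicker_gratings",
            length(counts) == nrow(stim$schedule))
  B <- build_temporal_basis(stim$frame_rate)
  L <- nrow(B); nb <- ncol(B)
  gid <- stim$schedule$grating_id
  gr <- stim$gratings
  valid <- seq_along(counts) > L
  y <- counts[valid]
  base <- list(x0 = 0, y0 = 0, sigma_x = 50, sigma_y = 50, theta_dog = 0,
               k_s = 2, w_surr = 0.5)
  for (nm in names(init)) base[[nm]] <- init[[nm]]
  # parameter vector: 7 spatial, nb centre coefs, nb surround coefs, b, log a
  p0 <- c(unlist(base), rep(0.1, nb), rep(-0.05, nb), 0,
          log(max(mean(y), 0.01)))
  nll_grad <- function(par, want_grad = TRUE) {
    sp <- as.list(par[1:7]); names(sp) <- names(base)
    cC <- par[7 + seq_len(nb)]; cS <- par[7 + nb + seq_len(nb)]
    b0 <- par[8 + 2 * nb]; a <- exp(par[9 + 2 * nb])
    ac <- st_frame_activations(sp, gr, gid, mode)
    XC <- lag_design(ac$actC, B); XS <- lag_design(ac$actS, B)
    d <- as.numeric(XC %*% cC + XS %*% cS) + b0
    Nd <- logistic(d)
    R <- pmax(a * Nd, 1e-10)
    nll <- sum(R[valid] - y * log(R[valid]))
    if (!want_grad) return(nll)
    gR <- numeric(length(d))
    gR[valid] <- 1 - y / R[valid]
    gd <- gR * a * Nd * (1 - Nd)
    gcC <- as.numeric(crossprod(XC, gd))
    gcS <- as.numeric(crossprod(XS, gd))
    gb <- sum(gd)
    gloga <- sum(gR * a * Nd)
    KC <- as.numeric(B %*% cC); KS <- as.numeric(B %*% cS)
    c0 <- amp_const(mode)
    f <- ac$f; th <- ac$th
    conv_back <- function(dact) {
      # sum_l (KC or KS)[l] * dact[t - l] for a given per-frame derivative
      n <- length(dact)
      out <- numeric(n)
      for (l in seq_len(L)) {
        idx <- (l + 1):n
        out[idx] <- out[idx] + dact[idx - l] * KCKS[l]
      }
      out
    }
    grad_sp <- numeric(7)
    dC <- list(  # derivatives of actC and actS/w_surr w.r.t. spatial params
      sigma_x = -c0 * f^2 * 2 * sp$sigma_x * cos(th + sp$theta_dog)^2,
      sigma_y = -c0 * f^2 * 2 * sp$sigma_y * sin(th + sp$theta_dog)^2,
      theta_dog = -c0 * f^2 * (sp$sigma_y^2 - sp$sigma_x^2) *
        sin(2 * (th + sp$theta_dog)))
    for (i in seq_len(7)) {
      nm <- names(base)[i]
      if (nm %in% c("sigma_x", "sigma_y", "theta_dog")) {
        dactC <- ac$E1 * dC[[nm]] * ac$cth
        dactS <- sp$w_surr * ac$E2 * sp$k_s^2 * dC[[nm]] * ac$cth
      } else if (nm == "x0") {
        dph <- -2 * pi * f * cos(th)
        dactC <- ac$E1 * ac$sth * dph
        dactS <- sp$w_surr * ac$E2 * ac$sth * dph
      } else if (nm == "y0") {
        dph <- -2 * pi * f * sin(th)
        dactC <- ac$E1 * ac$sth * dph
        dactS <- sp$w_surr * ac$E2 * ac$sth * dph
      } else if (nm == "k_s") {
        dactC <- 0 * f
        dactS <- sp$w_surr * ac$E2 *
          (-c0 * 2 * sp$k_s * ac$sig2 * f^2) * ac$cth
      } else {  # w_surr
        dactC <- 0 * f
        dactS <- ac$E2 * ac$cth
      }
      KCKS <- KC; convC <- conv_back(dactC)
      KCKS <- KS; convS <- conv_back(dactS)
      grad_sp[i] <- sum(gd * (convC + convS))
    }
    structure(nll, gradient = c(grad_sp, gcC, gcS, gb, gloga))
  }
  list(nll_grad = nll_grad, p0 = p0, nb = nb, B = B, base = base,
       lower = c(-500, -500, 7.51, 7.51, -pi / 4 + 1e-4, 1 + 1e-4, 0,
                 rep(-50, 2 * nb), -50, -10),
       upper = c(500, 500, 400, 400, pi / 4 - 1e-4, 6 - 1e-4, 1 - 1e-4,
                 rep(50, 2 * nb), 50, 10))
}

#' Fit a spatiotemporal DoG LN model to flickering gratings
#'
#' Maximum-likelihood fit of
#' `R = a * N(r_C' k_Ct + r_S' k_St + b)` where the temporal filters are
#' basis-coefficient expansions over [build_temporal_basis()]. Response bins
#' are stimulus frames; the first `n_lags` frames (incomplete history) are
#' excluded from the likelihood.
#'
#' @param stim A flicker battery from [make_grating_battery()].
#' @param counts Spike count per frame.
#' @param init Optional named list of spatial initial values.
#' @param mode Grating amplitude mode.
#' @param maxit L-BFGS-B iteration cap.
#' @return Object of class `st_dog_fit` with `spatial`, `c_C`, `c_S`
#'   (basis coefficients), `k_Ct`, `k_St` (expanded temporal filters), `a`,
#'   `b`, `nll`, `basis`.
#' @export
fit_st_dog_ln <- function(stim, counts, init = NULL, mode = "exact",
                          maxit = 300) {
  obj <- st_dog_objective(stim, counts, init = init, mode = mode)
  nb <- obj$nb; B <- obj$B; base <- obj$base
  nll_grad <- obj$nll_grad
  fn <- function(par) as.numeric(nll_grad(par, want_grad = FALSE))
  gr_fn <- function(par) attr(nll_grad(par, want_grad = TRUE), "gradient")
  parscale <- c(50, 50, 20, 20, 0.2, 1, 0.3, rep(1, 2 * nb), 1, 1)
  op <- stats::optim(obj$p0, fn, gr_fn, method = "L-BFGS-B",
                     lower = obj$lower, upper = obj$upper,
                     control = list(maxit = maxit, parscale = parscale))
  sp <- as.list(op$par[1:7]); names(sp) <- names(base)
  cC <- op$par[7 + seq_len(nb)]; cS <- op$par[7 + nb + seq_len(nb)]
  structure(list(spatial = sp, c_C = cC, c_S = cS,
                 k_Ct = as.numeric(B %*% cC), k_St = as.numeric(B %*% cS),
                 a = exp(op$par[9 + 2 * nb]), b = op$par[8 + 2 * nb],
                 nll = op$value, basis = B, mode = mode,
                 frame_rate = stim$frame_rate, converged = op$convergence == 0),
            class = "st_dog_fit")
}

#' Predict per-frame rates of a spatiotemporal DoG LN model
#'
#' @param fit An `st_dog_fit`.
#' @param stim A flicker battery.
#' @return Predicted spikes per frame (zero-padded history at the start).
#' @export
predict_st_dog_ln <- function(fit, stim) {
  ac <- st_frame_activations(fit$spatial, stim$gratings,
                             stim$schedule$grating_id, fit$mode)
  XC <- lag_design(ac$actC, fit$basis); XS <- lag_design(ac$actS, fit$basis)
  d <- as.numeric(XC %*% fit$c_C + XS %*% fit$c_S) + fit$b
  fit$a * logistic(d)
}

# ---- spatiotemporal subunit grid -------------------------------------------

#' Fit a spatiotemporal subunit grid model
#'
#' ADAM fit of `R = G( sum_s w_s N(r_C' k_Ct + r_S' k_St + gamma) )` on
#' flickering gratings, with circular DoG subunits on a hexagonal grid, the
#' density regularizer of [fit_sg()], contiguous-chunk batches (the reference
#' batch size for this variant is 2000 frames with peak learning rate 0.02),
#' and the Naka-Rushton output without baseline. Pruning and selection use the
#' same machinery as the flashed fits, with eligibility judged by training
#' log-likelihood.
#'
#' @param stim A flicker battery.
#' @param counts Spike count per frame.
#' @param centre_init Grid centre (µm).
#' @param config An [sg_config()]; `batch` is interpreted in frames
#'   (default here 2000) and `eta_max` defaults to 0.02.
#' @param mode Grating amplitude mode.
#' @return Object of class `st_sg_fit` with `params` (an [sg_params()] whose
#'   `out$b` is absent), `c_C`, `c_S`, `k_Ct`, `k_St`, `loglik`, `lambda`.
#' @export
fit_st_sg <- function(stim, counts, centre_init = c(0, 0),
                      config = sg_config(batch = 2000, eta_max = 0.02,
                                         n_sites = 300),
                      mode = "exact") {
  stopifnot(stim$kind == "flicker_gratings")
  B <- build_temporal_basis(stim$frame_rate)
  L <- nrow(B); nb <- ncol(B)
  gid <- stim$schedule$grating_id
  gr <- stim$gratings
  nfr <- length(counts)
  n_spikes <- sum(counts)
  if (n_spikes < 1) stop("no spikes in the data; cannot fit")
  grid <- subunit_grid(centre_init, config$n_sites, config$spacing)
  ns <- nrow(grid)
  dinv2 <- 1 / as.matrix(stats::dist(grid / 1000))^2
  diag(dinv2) <- 0
  cosT <- sg_cos_theta(grid, gr)[gid, , drop = FALSE]  # frames x subunits
  c0 <- amp_const(mode)
  f <- gr$f[gid]
  d2c <- (grid[, 1] - centre_init[1])^2 + (grid[, 2] - centre_init[2])^2
  w <- 0.5 * exp(-d2c / (2 * config$rf_sigma_init^2)) *
    with_seed(derive_seed(config$seed, 701L), stats::runif(ns, 0.5, 1.5))
  sigma <- config$sigma_init; k_s <- 2; w_surr <- 0.5; gamma <- 0
  cC <- c(0.3, 0.1, rep(0.05, nb - 2)); cS <- rep(-0.02, nb)
  out <- list(a = max(2 * mean(counts), 0.1), n = 2, k = 1)
  n_epochs <- config$n_epochs %||% max(1, round(4e5 / nfr))
  mth <- vth <- numeric(ns + 2 * nb + 7)
  # theta layout: w(ns), cC(nb), cS(nb), gamma, sigma, k_s, w_surr, a, n, k
  pack <- function() c(w, cC, cS, gamma, sigma, k_s, w_surr, out$a, out$n,
                       out$k)
  unpack <- function(th) {
    w <<- pmax(th[seq_len(ns)], 0)
    cC <<- th[ns + seq_len(nb)]; cS <<- th[ns + nb + seq_len(nb)]
    gamma <<- clamp(th[ns + 2 * nb + 1], -50, 50)
    sigma <<- clamp(th[ns + 2 * nb + 2], 7.51, 200)
    k_s <<- clamp(th[ns + 2 * nb + 3], 1 + 1e-3, 6 - 1e-3)
    w_surr <<- clamp(th[ns + 2 * nb + 4], 0, 1 - 1e-3)
    out <<- list(a = max(th[ns + 2 * nb + 5], 1e-6),
                 n = clamp(th[ns + 2 * nb + 6], 0.5, 8),
                 k = max(th[ns + 2 * nb + 7], 1e-3))
  }
  theta <- pack()
  chunk_starts <- seq(L + 1, nfr, by = config$batch)
  step <- 0
  for (ep in seq_len(n_epochs)) {
    eta <- config$eta_max * exp(-(ep - n_epochs / 2)^2 / (2 * (n_epochs / 5)^2))
    ord <- with_seed(derive_seed(config$seed, 703L, ep), sample(chunk_starts))
    for (cs in ord) {
      idx <- cs:min(cs + config$batch - 1, nfr)
      step <- step + 1
      g <- st_sg_chunk_grad(idx, counts[idx], cosT, f, c0, B, L, nb, ns,
                            w, cC, cS, gamma, sigma, k_s, w_surr, out,
                            dinv2, config$lambda,
                            (nfr - L) / (n_spikes * length(idx)))
      mth <- config$beta1 * mth + (1 - config$beta1) * g
      vth <- config$beta2 * vth + (1 - config$beta2) * g^2
      theta <- theta - eta * (mth / (1 - config$beta1^step)) /
        (sqrt(vth / (1 - config$beta2^step)) + config$eps)
      unpack(theta); theta <- pack()
    }
    if (!all(is.finite(theta))) stop("spatiotemporal subunit fit diverged")
  }
  params <- sg_params(grid, w, sigma = sigma, k_s = k_s, w_surr = w_surr,
                      beta = 1, gamma = gamma,
                      out = list(a = out$a, b = NULL, n = out$n, k = out$k),
                      mode = mode)
  pred <- predict_st_sg_core(seq_len(nfr), cosT, f, c0, B, L, w, cC, cS,
                             gamma, sigma, k_s, w_surr, out)
  valid <- seq_len(nfr) > L
  ll <- sum(counts[valid] * log(pmax(pred[valid], 1e-10)) -
              pred[valid]) - sum(lgamma(counts[valid] + 1))
  structure(list(params = params, c_C = cC, c_S = cS,
                 k_Ct = as.numeric(B %*% cC), k_St = as.numeric(B %*% cS),
                 loglik = ll, lambda = config$lambda, n_data = sum(valid),
                 basis = B, config = config, mode = mode),
            class = "st_sg_fit")
}

#' @keywords internal
predict_st_sg_core <- function(idx, cosT, f, c0, B, L, w, cC, cS, gamma,
                               sigma, k_s, w_surr, out) {
  E1 <- exp(-c0 * sigma^2 * f^2)
  E2 <- exp(-c0 * (k_s * sigma)^2 * f^2)
  KC <- as.numeric(B %*% cC); KS <- as.numeric(B %*% cS)
  Keff_C <- KC; Keff_S <- w_surr * KS
  nfr <- nrow(cosT)
  drive <- matrix(0, nfr, ncol(cosT))
  for (l in seq_len(L)) {
    src <- seq_len(nfr - l)
    amp <- Keff_C[l] * E1[src] + Keff_S[l] * E2[src]
    drive[src + l, ] <- drive[src + l, ] + amp * cosT[src, , drop = FALSE]
  }
  pooled <- pmax(as.numeric(logistic(drive + gamma) %*% w), 0)
  naka_rushton(pooled, c(out, list(b = 0)))
}

# Gradient of the chunk cost for the spatiotemporal subunit grid model.
#' @keywords internal
st_sg_chunk_grad <- function(idx, y, cosT, f, c0, B, L, nb, ns, w, cC, cS,
                             gamma, sigma, k_s, w_surr, out, dinv2, lambda,
                             scale) {
  lo <- max(1, min(idx) - L)
  span <- lo:max(idx)
  E1 <- exp(-c0 * sigma^2 * f[span]^2)
  E2 <- exp(-c0 * (k_s * sigma)^2 * f[span]^2)
  cT <- cosT[span, , drop = FALSE]
  KC <- as.numeric(B %*% cC); KS <- as.numeric(B %*% cS)
  off <- min(idx) - lo  # rows of span before the chunk
  nch <- length(idx)
  drive <- matrix(0, nch, ns)
  for (l in seq_len(L)) {
    src <- (off + seq_len(nch)) - l
    ok <- src >= 1
    amp <- KC[l] * E1[src[ok]] + w_surr * KS[l] * E2[src[ok]]
    drive[ok, ] <- drive[ok, ] + amp * cT[src[ok], , drop = FALSE]
  }
  Nz <- logistic(drive + gamma)
  u <- pmax(as.numeric(Nz %*% w), 0)
  un <- u^out$n; kn <- out$k^out$n; den <- un + kn
  G <- pmax(out$a * un / den, 1e-10)
  dG <- (1 - y / G) * scale
  dGdu <- ifelse(u > 0, out$a * out$n * u^(out$n - 1) * kn / den^2, 0)
  gu <- dG * dGdu
  P <- Nz * (1 - Nz)
  M <- (gu %o% w) * P
  gw <- as.numeric(crossprod(Nz, gu)) + 2 * lambda * as.numeric(dinv2 %*% w)
  ggamma <- sum(M)
  gKC <- numeric(L); gKS <- numeric(L)
  gsigma <- 0; gk_s <- 0; gw_surr <- 0
  dE1 <- -2 * c0 * sigma * f[span]^2 * E1
  dE2s <- -2 * c0 * k_s^2 * sigma * f[span]^2 * E2
  dE2k <- -2 * c0 * k_s * sigma^2 * f[span]^2 * E2
  for (l in seq_len(L)) {
    src <- (off + seq_len(nch)) - l
    ok <- src >= 1
    if (!any(ok)) next
    Ms <- M[ok, , drop = FALSE]
    cTs <- cT[src[ok], , drop = FALSE]
    rowdot <- rowSums(Ms * cTs)
    gKC[l] <- sum(rowdot * E1[src[ok]])
    gKS[l] <- w_surr * sum(rowdot * E2[src[ok]])
    gsigma <- gsigma + sum(rowdot * (KC[l] * dE1[src[ok]] +
                                       w_surr * KS[l] * dE2s[src[ok]]))
    gk_s <- gk_s + sum(rowdot * w_surr * KS[l] * dE2k[src[ok]])
    gw_surr <- gw_surr + sum(rowdot * KS[l] * E2[src[ok]])
  }
  gcC <- as.numeric(crossprod(B, gKC))
  gcS <- as.numeric(crossprod(B, gKS))
  ga <- sum(dG * un / den)
  gn <- sum(dG * ifelse(u > 0, out$a * kn * un * (log(u) - log(out$k)) / den^2,
                        0))
  gk <- sum(dG * (-out$a * out$n * un * out$k^(out$n - 1)) / den^2)
  c(gw, gcC, gcS, ggamma, gsigma, gk_s, gw_surr, ga, gn, gk)
}

#' Predict per-frame rates of a spatiotemporal subunit grid model
#'
#' @param fit An `st_sg_fit`.
#' @param stim A flicker battery (must match the fitted geometry).
#' @return Predicted spikes per frame.
#' @export
predict_st_sg <- function(fit, stim) {
  gid <- stim$schedule$grating_id
  cosT <- sg_cos_theta(fit$params$grid, stim$gratings)[gid, , drop = FALSE]
  predict_st_sg_core(seq_along(gid), cosT, stim$gratings$f[gid],
                     amp_const(fit$mode), fit$basis, nrow(fit$basis),
                     fit$params$w, fit$c_C, fit$c_S, fit$params$gamma,
                     fit$params$sigma, fit$params$k_s, fit$params$w_surr,
                     fit$params$out)
}
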