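# Prediction of responses to flashed natural images and natural videos from
# white-noise LN, DoG LN and subunit-grid models, model scoring, and
# identification of maximally differentiating fixations.

#' Pixel-space LN model
#'
#' A white-noise-derived LN model for natural-stimulus prediction: a spatial
#' filter at the stimulus pixel resolution and a temporal kernel over frames.
#'
#' @param spatial_filter Filter matrix at the target pixel resolution.
#' @param temporal_kernel Kernel over frame lags (lag 0 first); scalar 1 for
#'   flashed stimuli.
#' @param normalize Normalize the spatial filter by the sum of its absolute
#'   values (the convention used for natural-image prediction).
#' @return Object of class `ln_model`.
#' @export
ln_model <- function(spatial_filter, temporal_kernel = 1, normalize = TRUE) {
  if (normalize) spatial_filter <- spatial_filter / sum(abs(spatial_filter))
  structure(list(spatial_filter = spatial_filter,
                 temporal_kernel = temporal_kernel),
            class = "ln_model")
}

#' Build a pixel-resolution LN model from an STA decomposition
#'
#' Upsamples the white-noise spatial filter from stixel to target pixel
#' resolution (bilinear) and attaches the temporal filter (reversed into a
#' causal kernel over frame lags).
#'
#' @param sep A [separate_filters()] result.
#' @param sta_pitch Stixel size of the STA (µm).
#' @param target_pitch Target pixel size (µm).
#' @param temporal Use the temporal filter (`TRUE`) or an instantaneous
#'   kernel (`FALSE`).
#' @return An [ln_model()].
#' @export
ln_model_from_sta <- function(sep, sta_pitch, target_pitch, temporal = TRUE) {
  factor <- max(1L, round(sta_pitch / target_pitch))
  sp <- upsample_bilinear(sep$spatial, factor)
  tk <- if (temporal) sep$temporal else 1
  ln_model(sp, tk)
}

# Per-frame (or per-image) scalar model signal before any output
# nonlinearity; generic over model classes.
#' @keywords internal
model_signal <- function(model, frame_mat, pitch, shape) {
  if (inherits(model, "ln_model")) {
    ln_drive(list(spatial_filter = model$spatial_filter,
                  temporal_kernel = model$temporal_kernel), frame_mat)
  } else if (inherits(model, "dog_ln_fit")) {
    filt <- dog_filter_image(model$spatial, shape, pitch)
    as.numeric(frame_mat %*% as.numeric(filt))
  } else if (inherits(model, "sg_params") || inherits(model, "sg_fit")) {
    p <- if (inherits(model, "sg_fit")) model$params else model
    act <- which(p$w > 0)
    enc <- list(centres = p$grid[act, , drop = FALSE], sigma = p$sigma,
                k_s = p$k_s, w_surr = p$w_surr)
    filt <- sg_filter_matrix(enc, shape, pitch)
    su <- frame_mat %*% filt
    as.numeric(logistic(p$beta * su + p$gamma) %*% p$w[act])
  } else stop("unsupported model class for prediction")
}

#' Predict responses to flashed natural images
#'
#' Computes the model output for each image (filter output for LN and DoG LN
#' models; weighted sum of nonlinear subunit outputs for subunit-grid models;
#' no explicit output nonlinearity) and scores it by the Spearman rank
#' correlation with trial-mean spike counts.
#'
#' @param model An [ln_model()], `dog_ln_fit`, `sg_fit` or [sg_params()].
#' @param images List of contrast images at single-pixel resolution.
#' @param responses Trial-mean spike count per image (same order), or `NULL`
#'   to return the model output only.
#' @param pixel_pitch Image pixel size (µm).
#' @return List of class `prediction_result` with `output`, `rho` (0 with
#'   `degenerate = TRUE` when either variable is constant) and `n`.
#' @export
predict_images <- function(model, images, responses = NULL, pixel_pitch) {
  sh <- dim(images[[1]])
  fm <- t(vapply(images, as.numeric, numeric(prod(sh))))
  out <- model_signal(model, fm, pixel_pitch, sh)
  res <- list(output = out, n = length(images))
  if (!is.null(responses)) {
    stopifnot(length(responses) == length(images))
    degenerate <- stats::sd(out) == 0 || stats::sd(responses) == 0
    res$rho <- if (degenerate) 0
               else stats::cor(out, responses, method = "spearman")
    res$degenerate <- degenerate
  }
  class(res) <- "prediction_result"
  res
}

#' Equal-population histogram nonlinearity
#'
#' Estimates a static output nonlinearity as a histogram over the model
#' signal: `n_bins` bins containing (as nearly as possible) the same number of
#' training points, each storing the average signal and the average spike
#' count. Applied by linear interpolation, clamped to the end-bin values
#' outside the training range.
#'
#' @param signal Training model signal.
#' @param counts Training spike counts (same length).
#' @param n_bins Number of equal-count bins.
#' @return Object of class `histogram_nl` with fields `x`, `y`; apply with
#'   [apply_histogram_nl()].
#' @export
fit_histogram_nl <- function(signal, counts, n_bins = 40) {
  stopifnot(length(signal) == length(counts), length(signal) >= n_bins)
  ord <- order(signal)
  bin <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  x <- as.numeric(tapply(signal[ord], bin, mean))
  y <- as.numeric(tapply(counts[ord], bin, mean))
  structure(list(x = x, y = y, n_bins = n_bins,
                 bin_counts = as.numeric(table(bin))),
            class = "histogram_nl")
}

#' @rdname fit_histogram_nl
#' @param nl A `histogram_nl`.
#' @param signal Signal values to transform.
#' @export
apply_histogram_nl <- function(nl, signal) {
  stats::approx(nl$x, nl$y, xout = signal, rule = 2)$y
}

#' Predict natural-video responses and score them
#'
#' Computes the model signal on training and test segments of a video,
#' estimates an output nonlinearity on the training segment (equal-population
#' histogram for white-noise LN models; Poisson maximum-likelihood refit of
#' the model's parametric output form for grating-fitted models), and scores
#' the test-segment prediction by the fraction of explained variance R²
#' (negative values clipped to zero) against the trial-averaged test firing
#' rate. Cells should be gated upstream on an even/odd symmetrized R² of at
#' least 0.2 on the test segment.
#'
#' @param model A model object (see [predict_images()]).
#' @param video A `stimulus_set` of kind `"video"`.
#' @param raster_train A [spike_raster()] over the training frames (1 or more
#'   trials).
#' @param raster_test A [spike_raster()] over the test frames (repeated
#'   trials).
#' @param train_frames,test_frames Frame indices of the two disjoint
#'   segments.
#' @param nonlinearity `"histogram"` or `"refit"` (parametric ML refit).
#' @return `prediction_result` with `predicted_rate` (test segment),
#'   `r2` (clipped), `r2_raw`, the fitted `output_nonlinearity`, and
#'   `test_rate`.
#' @export
predict_video <- function(model, video, raster_train, raster_test,
                          train_frames, test_frames,
                          nonlinearity = c("histogram", "refit")) {
  nonlinearity <- match.arg(nonlinearity)
  if (length(intersect(train_frames, test_frames)))
    stop("training and test segments must be disjoint")
  if (!length(train_frames)) stop("empty training segment")
  fm <- stimulus_frame_matrix(video)
  sig <- model_signal(model, fm, video$pixel_pitch, video$crop)
  sig_train <- sig[train_frames]; sig_test <- sig[test_frames]
  y_train <- colMeans(raster_train$counts)
  stopifnot(length(y_train) == length(train_frames))
  if (nonlinearity == "histogram") {
    nl <- fit_histogram_nl(sig_train, y_train)
    pred <- apply_histogram_nl(nl, sig_test)
  } else {
    nl <- fit_parametric_output_nl(model, sig_train, y_train)
    pred <- nl$fun(sig_test)
  }
  test_rate <- colMeans(raster_test$counts)
  stopifnot(length(test_rate) == length(test_frames))
  ss_res <- sum((test_rate - pred)^2)
  ss_tot <- sum((test_rate - mean(test_rate))^2)
  r2_raw <- 1 - ss_res / ss_tot
  structure(list(predicted_rate = pred, test_rate = test_rate,
                 r2 = max(r2_raw, 0), r2_raw = r2_raw,
                 output_nonlinearity = nl),
            class = "prediction_result")
}

# Poisson ML refit of the model's own parametric output nonlinearity on the
# training signal: a*logistic(beta*x + gamma) for LN-type models,
# Naka-Rushton for subunit-grid models (signal is non-negative there).
#' @keywords internal
fit_parametric_output_nl <- function(model, signal, counts) {
  if (inherits(model, "sg_params") || inherits(model, "sg_fit")) {
    obj <- function(th) {
      out <- list(a = exp(th[1]), b = exp(th[2]),
                  n = clamp(exp(th[3]), 0.5, 8), k = exp(th[4]))
      poisson_nll(naka_rushton(signal, out), counts)
    }
    op <- stats::optim(c(log(max(mean(counts) * 2, 1e-3)), log(1e-3),
                         log(2), log(max(stats::median(signal), 1e-3))),
                       obj, method = "Nelder-Mead",
                       control = list(maxit = 2000))
    out <- list(a = exp(op$par[1]), b = exp(op$par[2]),
                n = clamp(exp(op$par[3]), 0.5, 8), k = exp(op$par[4]))
    list(type = "naka_rushton", params = out,
         fun = function(x) naka_rushton(x, out))
  } else {
    sc <- stats::sd(signal); if (sc == 0) sc <- 1
    obj <- function(th) {
      r <- exp(th[1]) * logistic(th[2] * (signal / sc) + th[3])
      poisson_nll(r, counts)
    }
    op <- stats::optim(c(log(max(mean(counts) * 2, 1e-3)), 2, 0), obj,
                       method = "Nelder-Mead", control = list(maxit = 2000))
    pars <- op$par
    list(type = "scaled_logistic",
         params = list(a = exp(pars[1]), beta = pars[2] / sc,
                       gamma = pars[3]),
         fun = function(x) exp(pars[1]) * logistic(pars[2] * (x / sc) +
                                                     pars[3]))
  }
}

#' Maximally differentiating fixations
#'
#' Scores each fixation of a cell pair by how much the predictions of a
#' spatially nonlinear model (subunit grid) and a spatially linear model
#' (DoG LN) diverge: the absolute prediction difference per frame, normalized
#' by each cell's overall response range over the test segment
#' (max minus min of the trial-averaged rate), averaged over fixation frames
#' and over the two cells. The top 20% of fixations form the maximally
#' differentiating set; the upper half forms the "nonlinear" group and the
#' lower half the "linear" group. Selection uses only the prediction
#' difference (response ranges are permutation-invariant), never the data.
#'
#' @param pred_sg,pred_dog Lists of two per-frame prediction vectors (one per
#'   cell) over the test segment.
#' @param rates List of two trial-averaged test firing-rate vectors.
#' @param fixations Fixation table (frames indexed within the test segment).
#' @param top_frac Fraction of fixations in the top set.
#' @return List of class `diff_fixations` with `scores`, `top_set`,
#'   `nonlinear_set`, `linear_set`, per-model `r2_top` (mean over the two
#'   cells on top-set frames), and `uninformative` flag when all scores are
#'   zero.
#' @export
differentiating_fixations <- function(pred_sg, pred_dog, rates, fixations,
                                      top_frac = 0.2) {
  n_fix <- nrow(fixations)
  if (n_fix < 5) warning("fewer than 5 fixations; top set is degenerate")
  rng <- vapply(rates, function(r) max(r) - min(r), numeric(1))
  rng[rng == 0] <- 1
  scores <- vapply(seq_len(n_fix), function(i) {
    fr <- seq.int(fixations$start_frame[i], fixations$end_frame[i] - 1L)
    mean(vapply(1:2, function(ci) {
      mean(abs(pred_sg[[ci]][fr] - pred_dog[[ci]][fr])) / rng[ci]
    }, numeric(1)))
  }, numeric(1))
  ord <- order(-scores, seq_len(n_fix))  # ties broken by fixation index
  n_top <- ceiling(top_frac * n_fix)
  top_set <- sort(ord[seq_len(n_top)])
  half <- floor(n_fix / 2)
  nonlinear_set <- sort(ord[seq_len(half)])
  linear_set <- sort(setdiff(seq_len(n_fix), nonlinear_set))
  top_frames <- unlist(lapply(top_set, function(i)
    seq.int(fixations$start_frame[i], fixations$end_frame[i] - 1L)))
  r2_top <- function(pred) {
    mean(vapply(1:2, function(ci) {
      y <- rates[[ci]][top_frames]; p <- pred[[ci]][top_frames]
      max(1 - sum((y - p)^2) / sum((y - mean(y))^2), 0)
    }, numeric(1)))
  }
  structure(list(scores = scores, top_set = top_set,
                 nonlinear_set = nonlinear_set, linear_set = linear_set,
                 r2_top_sg = r2_top(pred_sg), r2_top_dog = r2_top(pred_dog),
                 uninformative = all(scores == 0)),
            class = "diff_fixations")
}
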