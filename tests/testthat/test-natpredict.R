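test_that("the histogram nonlinearity uses equal-count bins and clamps", {
  set.seed(41)
  sig <- rnorm(4000); counts <- pmax(sig, 0) + rnorm(4000, sd = 0.1)
  nl <- fit_histogram_nl(sig, counts, n_bins = 40)
  expect_equal(length(nl$x), 40)
  expect_true(max(nl$bin_counts) - min(nl$bin_counts) <= 1)
  # clamped to end-bin values outside the training range
  expect_equal(apply_histogram_nl(nl, 100), nl$y[40])
  expect_equal(apply_histogram_nl(nl, -100), nl$y[1])
  # interpolation is exact at the bin centres
  expect_equal(apply_histogram_nl(nl, nl$x[7]), nl$y[7])
})

test_that("image prediction scores are rank-invariant and flag degeneracy", {
  imgs <- make_natural_images(30, shape = c(40, 40), seed = 42)
  sp <- dog_spatial(0, 0, 40, 40, 0, 2, 0.4)
  fit <- structure(list(spatial = sp, beta = 3, gamma = -1, a = 5,
                        mode = "exact"), class = "dog_ln_fit")
  # responses generated by a monotone transform of the model output:
  # Spearman rho = 1 exactly
  out <- predict_images(fit, imgs, responses = NULL, pixel_pitch = 7.5)$output
  res <- predict_images(fit, imgs, responses = exp(2 * out), pixel_pitch = 7.5)
  expect_equal(res$rho, 1)
  res2 <- predict_images(fit, imgs, responses = exp(out)^3, pixel_pitch = 7.5)
  expect_equal(res2$rho, res$rho)
  # constant responses: degenerate, reported as 0 with a flag
  resd <- predict_images(fit, imgs, responses = rep(2, 30), pixel_pitch = 7.5)
  expect_true(resd$degenerate)
  expect_equal(resd$rho, 0)
})

test_that("subunit models outrank a mismatched linear model on contrast-driven responses", {
  imgs <- make_natural_images(40, shape = c(40, 40), envelope_strength = 1.2,
                              seed = 43)
  enc <- sg_encoder(subunit_grid(c(0, 0), 19, 32), w = rep(1, 19), sigma = 15,
                    k_s = 2, w_surr = 0.8, beta = 8, gamma = -2,
                    out = list(a = 50, b = 1, n = 2, k = 3))
  stim <- make_flashed_images(imgs, n_trials = 6, pixel_pitch = 7.5, seed = 44)
  rasts <- simulate_responses(population(list(enc)), stim, seed = 45)
  counts <- rasts[[1]]$counts[1, ]
  mean_per_image <- as.numeric(tapply(counts, stim$schedule$image_id, mean))
  p <- sg_params(enc$centres, enc$w, sigma = enc$sigma, k_s = enc$k_s,
                 w_surr = enc$w_surr, beta = enc$beta, gamma = enc$gamma,
                 out = enc$out)
  rho_sg <- predict_images(p, imgs, mean_per_image, pixel_pitch = 7.5)$rho
  lin <- ln_model(dog_filter_image(dog_spatial(0, 0, 55, 55, 0, 2, 0.2),
                                   c(40, 40), 7.5))
  rho_lin <- predict_images(lin, imgs, mean_per_image, pixel_pitch = 7.5)$rho
  expect_gt(abs(rho_sg), abs(rho_lin))
})

test_that("video prediction gates on disjoint segments and clips R2", {
  imgs <- make_natural_images(8, shape = c(60, 60), seed = 46)
  video <- make_gaze_video(imgs, gaze_model(jitter_sd_um = 4,
                                            saccades_per_image = 0),
                           frame_rate = 75, pixel_pitch = 7.5,
                           crop = c(40, 40), seed = 47)
  n <- nrow(video$schedule)
  train <- 1:450; test <- 451:n
  enc <- dog_ln_encoder(dog_spatial(0, 0, 40, 40, 0, 2, 0.4), beta = 10,
                        gamma = -1, a = 80)
  rasts <- simulate_responses(population(list(enc)), video, n_trials = 60,
                              seed = 48)
  rtrain <- spike_raster(rasts[[1]]$counts[, train, drop = FALSE],
                         rasts[[1]]$bin_width)
  rtest <- spike_raster(rasts[[1]]$counts[, test, drop = FALSE],
                        rasts[[1]]$bin_width)
  fit <- structure(list(spatial = enc$spatial, beta = enc$beta,
                        gamma = enc$gamma, a = enc$a, mode = "exact"),
                   class = "dog_ln_fit")
  res <- predict_video(fit, video, rtrain, rtest, train, test,
                       nonlinearity = "refit")
  expect_gt(res$r2, 0.5)    # true model, many trials: high explained variance
  # shuffled predictions: R2 clipped to zero
  sh <- res
  set.seed(1)
  shuffled_rate <- sample(res$test_rate)
  ss_res <- sum((res$test_rate - shuffled_rate)^2)
  ss_tot <- sum((res$test_rate - mean(res$test_rate))^2)
  expect_lt(1 - ss_res / ss_tot, 0.05)
  expect_error(predict_video(fit, video, rtrain, rtest, train,
                             c(450, test)), "disjoint")
})

test_that("differentiating fixations rank by prediction divergence only", {
  fix <- data.frame(fixation = 1:10,
                    start_frame = seq(1, 91, by = 10),
                    end_frame = seq(11, 101, by = 10))
  n <- 100
  base <- sin(seq(0, 6 * pi, length.out = n)) + 2
  pred_dog <- list(base, base)
  pred_sg <- list(base, base)
  # plant divergence in fixations 3 and 8
  for (i in c(3, 8)) {
    fr <- fix$start_frame[i]:(fix$end_frame[i] - 1)
    pred_sg[[1]][fr] <- pred_sg[[1]][fr] + 1
    pred_sg[[2]][fr] <- pred_sg[[2]][fr] + 1.5
  }
  rates <- list(base + rnorm(n, sd = 0.01), base + rnorm(n, sd = 0.01))
  df <- differentiating_fixations(pred_sg, pred_dog, rates, fix)
  expect_equal(df$top_set, c(3, 8))               # ceil(0.2 * 10) = 2
  expect_equal(length(df$top_set), 2)
  expect_true(all(c(3, 8) %in% df$nonlinear_set))
  expect_setequal(c(df$nonlinear_set, df$linear_set), 1:10)
  expect_equal(length(intersect(df$nonlinear_set, df$linear_set)), 0)
  # selection neutrality: permuting the responses leaves the sets unchanged
  perm <- lapply(rates, sample)
  df2 <- differentiating_fixations(pred_sg, pred_dog, perm, fix)
  expect_equal(df2$top_set, df$top_set)
  expect_equal(df2$nonlinear_set, df$nonlinear_set)
  # identical predictions: all scores zero, flagged uninformative
  df0 <- differentiating_fixations(pred_dog, pred_dog, rates, fix)
  expect_true(df0$uninformative)
  expect_true(all(df0$scores == 0))
})
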