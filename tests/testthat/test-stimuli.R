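test_that("grating rendering matches the pixel-wise sinusoid definition", {
  # f = 0, phi = pi/2: sin(pi/2) = 1 everywhere
  m <- render_grating(grating_spec(0, 1.1, pi / 2), c(5, 7), 7.5)
  expect_equal(m, matrix(1, 5, 7))
  # zero phase, horizontal grating: x = 0 column sits at sin(0) = 0
  m2 <- render_grating(grating_spec(1 / 30, 0, 0), c(5, 5), 15)
  expect_equal(m2[, 3], rep(0, 5))
  # direct scalar substitution at a pixel centre
  sp <- grating_spec(1 / 240, pi / 4, pi / 3)
  m3 <- render_grating(sp, c(17, 17), 7.5)
  x <- (12 - 9) * 7.5; y <- (14 - 9) * 7.5   # pixel (14, 12): x col, y row
  expect_equal(m3[14, 12],
               sin(2 * pi / 240 * (x * cos(pi / 4) + y * sin(pi / 4)) + pi / 3))
  expect_true(all(abs(m3) <= 1))
  expect_error(render_grating(list(f = NaN, theta = 0, phi = 0), c(4, 4), 7.5))
})

test_that("grating battery layout and flicker frozen segments behave", {
  stim <- make_grating_battery(c(0.001, 0.01), c(0, pi / 2), c(0, pi),
                               layout = "flashed", n_trials = 3,
                               frame_rate = 85, flash_ms = 200, gap_ms = 800)
  expect_equal(nrow(stim$gratings), 8)
  expect_equal(nrow(stim$schedule), 24)
  expect_equal(stim$flash_frames, 17)  # 200 ms at 85 Hz
  # each trial presents every grating exactly once
  for (tr in 1:3)
    expect_setequal(stim$schedule$grating_id[stim$schedule$trial == tr], 1:8)
  # the classical parameter counts: 25 x 12 x 4 = 1200 distinct gratings
  big <- reference_battery(n_trials = 1)
  expect_equal(nrow(big$gratings), 1200)

  fl <- make_grating_battery(c(0.001, 0.01), c(0, pi / 2), c(0, pi),
                             layout = "flicker", n_frames = 3000,
                             frozen_every = 1000, frozen_length = 200)
  expect_equal(nrow(fl$schedule), 3000)
  frozen1 <- fl$schedule$grating_id[fl$schedule$frozen_cycle == 1]
  frozen2 <- fl$schedule$grating_id[fl$schedule$frozen_cycle == 2]
  expect_identical(frozen1, frozen2)  # bit-identical frozen repeats
})

test_that("checkerboard is reproducible, binary and mean-zero", {
  a <- make_checkerboard(30, 7.5, c(10, 10), 30, duration_s = 20, seed = 3)
  b <- make_checkerboard(30, 7.5, c(10, 10), 30, duration_s = 20, seed = 3)
  expect_identical(a$frames, b$frames)
  expect_setequal(unique(as.numeric(a$frames)), c(-1, 1))
  # binomial CI on the long-run mean contrast
  n <- length(a$frames)
  expect_lt(abs(mean(a$frames)), 4 / sqrt(n))
  expect_error(make_checkerboard(20, 7.5), "multiple")
})

test_that("gaze videos keep their bookkeeping and degenerate limits", {
  imgs <- make_natural_images(4, shape = c(60, 60), seed = 2)
  still <- make_gaze_video(imgs, gaze_model(jitter_sd_um = 0,
                                            saccades_per_image = 0),
                           frame_rate = 75, pixel_pitch = 7.5,
                           crop = c(40, 40), seed = 9)
  expect_equal(nrow(still$schedule), 4 * 75)
  expect_equal(sum(still$schedule$transition), 4)
  # zero jitter and no saccades: frames within one presentation identical
  expect_identical(video_frame(still, 2), video_frame(still, 70))
  expect_false(identical(video_frame(still, 2), video_frame(still, 80)))
  # schedule length equals frame count; regeneration is bit-identical
  again <- make_gaze_video(imgs, gaze_model(jitter_sd_um = 0,
                                            saccades_per_image = 0),
                           frame_rate = 75, pixel_pitch = 7.5,
                           crop = c(40, 40), seed = 9)
  expect_identical(still$schedule, again$schedule)
  expect_error(make_gaze_video(imgs, gaze_model(jitter_sd_um = 200),
                               crop = c(58, 58), pixel_pitch = 7.5,
                               overflow = "error", seed = 1),
               "padding")
})

test_that("natural-like images hit the target contrast statistics", {
  imgs <- make_natural_images(6, shape = c(80, 80), rms_contrast = 0.45,
                              seed = 4)
  sds <- vapply(imgs, stats::sd, numeric(1))
  expect_true(all(abs(sds - 0.45) < 0.08))  # clipping erodes the SD slightly
  expect_true(all(vapply(imgs, function(m) max(abs(m)) <= 1, logical(1))))
  # the contrast envelope makes local contrast patchy across the image
  local_sd <- function(m) {
    blocks <- expand.grid(i = 0:3, j = 0:3)
    vapply(seq_len(nrow(blocks)), function(b)
      stats::sd(m[blocks$i[b] * 20 + 1:20, blocks$j[b] * 20 + 1:20]),
      numeric(1))
  }
  spread <- vapply(imgs, function(m) {
    s <- local_sd(m); stats::sd(s) / mean(s)
  }, numeric(1))
  expect_gt(mean(spread), 0.2)
})

test_that("Poisson simulation is calibrated and seed-stable", {
  stim <- make_checkerboard(30, 7.5, c(8, 8), 30, duration_s = 10, seed = 6)
  enc <- ln_encoder(matrix(0, 8, 8), nonlinearity = "softplus", gain = 1,
                    threshold = 0.5, rate_scale = 30)  # constant rate
  pop <- population(list(enc))
  r1 <- simulate_responses(pop, stim, n_trials = 200, seed = 11)[[1]]
  r2 <- simulate_responses(pop, stim, n_trials = 200, seed = 11)[[1]]
  expect_identical(r1$counts, r2$counts)
  rate <- attr(r1, "rate")[1]
  mu <- rate / 30  # per-frame mean
  total <- rowSums(r1$counts)
  t_tot <- ncol(r1$counts) / 30
  expect_lt(abs(mean(total) - rate * t_tot), 4 * sqrt(rate * t_tot / 200))
  # per-bin variance/mean (Fano) ~ 1 within chi-square-ish bounds
  fano <- apply(r1$counts, 2, stats::var) / pmax(colMeans(r1$counts), 1e-12)
  expect_lt(abs(mean(fano) - 1), 0.05)
  # adding a cell must not reshuffle the first cell's streams
  pop2 <- population(list(enc, ln_encoder(matrix(0, 8, 8), gain = 1,
                                          rate_scale = 10, centre = c(50, 0))))
  r1b <- simulate_responses(pop2, stim, n_trials = 200, seed = 11)[[1]]
  expect_identical(r1$counts, r1b$counts)
  # zero rate gives an all-zero raster
  enc0 <- ln_encoder(matrix(0, 8, 8), nonlinearity = "linear", gain = 1,
                     threshold = 0, rate_scale = 1)
  r0 <- simulate_responses(population(list(enc0)), stim, n_trials = 3,
                           seed = 2)[[1]]
  expect_true(all(r0$counts == 0))
})

test_that("rate upsampling preserves the piecewise-constant trace", {
  rate <- c(10, 20, 30)
  up <- upsample_rate(rate, frame_rate = 10, bin_width = 0.01)
  expect_equal(length(up), 30)
  expect_equal(up[1:10], rep(10, 10))
  expect_equal(up[21:30], rep(30, 10))
})
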