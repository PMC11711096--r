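test_that("fixation detection splits on transitions and velocity peaks", {
  # zero motion, 10 images x 1 s at 75 Hz: exactly 10 fixations
  pos <- matrix(0, 750, 2)
  fix <- detect_fixations(pos, frame_rate = 75,
                          transitions = seq(1, 750, by = 75))
  expect_equal(nrow(fix), 10)
  expect_true(all(fix$source == "transition"))
  # fixations tile the trace without overlap
  expect_equal(fix$start_frame[-1], fix$end_frame[-nrow(fix)])
  expect_equal(fix$end_frame[nrow(fix)], 751)

  # one planted 400 deg/s step (threshold 300 deg/s): image splits in two
  pos2 <- matrix(0, 150, 2)
  pos2[80:150, 1] <- 400 * 31 / 75   # step of 400 deg/s at 31 um/deg, 75 Hz
  fix2 <- detect_fixations(pos2, frame_rate = 75, transitions = c(1, 76),
                           min_interval_ms = 53, min_amplitude = 300,
                           retinal_magnification = 31)
  expect_equal(nrow(fix2), 3)
  expect_equal(attr(fix2, "saccade_frames"), 80)
})

test_that("close velocity peaks keep only the taller one", {
  # two peaks 30 ms apart (min interval 53 ms), amplitudes 400 and 500 deg/s
  fr <- 75
  pos <- matrix(0, 150, 2)
  step1 <- 400 * 31 / fr; step2 <- 500 * 31 / fr
  pos[50:150, 1] <- step1
  pos[52:150, 1] <- step1 + step2   # second peak ~27 ms later, taller
  fix <- detect_fixations(pos, frame_rate = fr, transitions = 1,
                          min_interval_ms = 53, min_amplitude = 300,
                          retinal_magnification = 31)
  expect_equal(attr(fix, "saccade_frames"), 52)  # only the 500 deg/s peak
  expect_equal(nrow(fix), 2)
})

test_that("planted saccades are recovered with perfect precision and recall", {
  imgs <- make_natural_images(8, shape = c(100, 100), seed = 51)
  video <- make_gaze_video(imgs, gaze_model(jitter_sd_um = 1.5,
                                            saccades_per_image = 1,
                                            saccade_amp_um = c(100, 200)),
                           frame_rate = 85, pixel_pitch = 7.5,
                           crop = c(60, 60), seed = 52)
  # planted amplitudes >= 100 um in one 1/85 s frame = 8500 um/s = 85 deg/s
  # at 100 um/deg: use half that as detection threshold (>= 2x margin)
  fix <- detect_fixations(video$gaze,
                          transitions = which(video$schedule$transition),
                          min_interval_ms = 47, min_amplitude = 42.5,
                          retinal_magnification = 100)
  detected <- attr(fix, "saccade_frames")
  expect_setequal(detected, video$gaze$saccade_frames)
})

test_that("spatial contrast is a weighted SD with the right invariances", {
  fix <- data.frame(fixation = 1, start_frame = 1, end_frame = 3)
  w <- matrix(c(2, 1, 1, 0), 2, 2)
  # uniform frame: SC = 0
  fm <- rbind(rep(0.5, 4), c(1, -1, 1, -1))
  sca <- spatial_contrast_and_activation(
    structure(fm, shape = c(2, 2), pitch = 7.5), fix, w)
  sc_frames <- attr(sca, "sc_frame")
  expect_equal(sc_frames[1], 0)
  # closed-form weighted SD for the two-level frame
  wn <- pmax(as.numeric(w), 0); wn <- wn / sum(wn)
  p <- c(1, -1, 1, -1)
  mu <- sum(wn * p)
  expect_equal(sc_frames[2], sqrt(sum(wn * (p - mu)^2)))
  # homogeneity: scaling contrast by c scales SC and activation by c
  sca3 <- spatial_contrast_and_activation(
    structure(3 * fm, shape = c(2, 2), pitch = 7.5), fix, w)
  expect_equal(attr(sca3, "sc_frame"), 3 * sc_frames)
  expect_equal(attr(sca3, "act_frame"), 3 * attr(sca, "act_frame"))
})

test_that("the contrast split balances activation and recovers planted labels", {
  n <- 80
  # constructed fixture: activation ordering alternates the planted SC
  # labels, so each activation-matched pair holds one low and one high label
  act <- as.numeric(seq_len(n))
  sc <- rep(c(0.1, 0.9), n / 2)
  fa <- data.frame(fixation = 1:n, spatial_contrast = sc,
                   linear_activation = act)
  sp <- split_by_spatial_contrast(fa, fa)
  expect_equal(sp$n_pairs, 40)           # 80 fixations -> 40 pairs, 40/40
  expect_equal(length(sp$high), 40)
  expect_equal(length(sp$low), 40)
  expect_true(all(sc[sp$high] == 0.9))   # planted labels recovered exactly
  # with random activation the groups stay activation-balanced
  set.seed(53)
  fb <- data.frame(fixation = 1:n, spatial_contrast = runif(n),
                   linear_activation = rnorm(n))
  spb <- split_by_spatial_contrast(fb, fb)
  expect_lt(abs(mean(fb$linear_activation[spb$high]) -
                  mean(fb$linear_activation[spb$low])),
            0.1 * stats::sd(fb$linear_activation) + 0.2)
  # ties split deterministically by fixation index
  ft <- data.frame(fixation = 1:4, spatial_contrast = rep(0.5, 4),
                   linear_activation = c(1, 1.1, 2, 2.1))
  spt <- split_by_spatial_contrast(ft, ft)
  expect_equal(spt$high, c(1, 3))
  # odd fixation counts drop the last sorted fixation
  fo <- fa[1:79, ]
  spo <- split_by_spatial_contrast(fo, fo)
  expect_equal(spo$n_pairs, 39)
})

test_that("partial correlations reproduce the hand-computed example", {
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  manual <- sum((x[1:2] - mean(x)) * (y[1:2] - mean(y))) /
    (3 * stats::sd(x) * stats::sd(y))
  expect_equal(partial_correlation(x, y, 1:2), manual)
  expect_equal(partial_correlation(x, y, integer(0)), 0)
  expect_equal(partial_correlation(x, y, 1:4), stats::cor(x, y))
  expect_equal(partial_correlation(x, y, 1:2) +
                 partial_correlation(x, y, 3:4), stats::cor(x, y))
  expect_error(partial_correlation(rep(1, 4), y, 1:2), "zero variance")
})

test_that("decomposition identities hold to a few ulp on random fixtures", {
  set.seed(54)
  worst <- 0
  for (rep in 1:1000) {
    n <- sample(20:200, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.3 * x
    subset <- sample(n, sample(0:n, 1))
    r_a <- partial_correlation(x, y, subset)
    r_b <- partial_correlation(x, y, setdiff(seq_len(n), subset))
    worst <- max(worst, abs(r_a + r_b - stats::cor(x, y)))
  }
  expect_lt(worst, 4 * .Machine$double.eps * 100)
})

test_that("correlation-distance curves and decorrelation behave", {
  set.seed(55)
  base <- rnorm(500)
  rates <- list(base + rnorm(500, sd = 0.3),
                base + rnorm(500, sd = 0.3),
                rnorm(500),
                rep(1, 500))                    # degenerate cell
  centres <- rbind(c(0, 0), c(50, 0), c(300, 0), c(400, 0))
  res <- correlation_vs_distance(rates, centres, group_size = 2)
  expect_true(res$pairs$degenerate[res$pairs$j == 4][1])
  r12 <- res$pairs$correlation[res$pairs$i == 1 & res$pairs$j == 2]
  expect_gt(r12, 0.8)
  r13 <- res$pairs$correlation[res$pairs$i == 1 & res$pairs$j == 3]
  expect_lt(abs(r13), 0.2)
  # decorrelation: duplicated cell at distance 0 -> 0; independent -> ~1
  interp <- function(d) stats::approx(c(0, 500), c(1, 0.5), xout = d,
                                      rule = 2)$y
  expect_equal(decorrelation(1, 0, interp), 0)
  expect_equal(decorrelation(0, 300, interp), 1)
})

test_that("stimulus pixel correlations fall with distance and match brute force", {
  imgs <- make_natural_images(10, shape = c(80, 80), seed = 56)
  video <- make_gaze_video(imgs, gaze_model(jitter_sd_um = 3,
                                            saccades_per_image = 1),
                           frame_rate = 30, pixel_pitch = 7.5,
                           crop = c(60, 60), seed = 57)
  res <- stimulus_pixel_correlation(video, n_pixels = 60, seed = 58)
  cv <- res$curve
  expect_gt(mean(cv$correlation[1:3]), mean(cv$correlation[(nrow(cv) - 2):nrow(cv)]))
  expect_equal(res$interp(0), 1)
  # brute-force oracle on a small subsample
  fm <- rgcpop:::stimulus_frame_matrix(video)
  set.seed(58)
  sel <- sample(ncol(fm), 25)
  sel <- sel[apply(fm[, sel], 2, stats::sd) > 0]
  cm <- stats::cor(fm[, sel])
  sh <- attr(fm, "shape")
  rows <- (sel - 1) %% sh[1] + 1; cols <- (sel - 1) %/% sh[1] + 1
  dmat <- as.matrix(stats::dist(cbind(cols, rows) * 7.5))
  near <- dmat > 0 & dmat < 40
  far <- dmat > 300
  expect_gt(mean(cm[near]), mean(cm[far]))
})

test_that("direction selectivity metrics match their closed forms", {
  dirs <- seq(0, 2 * pi, length.out = 9)[1:8]
  # all spikes in one direction: DSI = 1
  one <- matrix(0, 5, 8); one[, 3] <- 4
  expect_equal(direction_selectivity(one, dirs, n_perm = 99)$dsi, 1)
  # equal responses everywhere: DSI = 0
  eq <- matrix(2, 5, 8)
  expect_equal(direction_selectivity(eq, dirs, n_perm = 99)$dsi, 0)
  # r = (2, 1, 0, 1) over the four cardinal directions: DSI = 0.5, pref 0
  quad <- matrix(rep(c(2, 1, 0, 1), each = 6), 6, 4)
  res <- direction_selectivity(quad, c(0, pi / 2, pi, 3 * pi / 2),
                               n_perm = 199, seed = 3)
  expect_equal(res$dsi, 0.5)
  expect_equal(res$preferred_direction, 0)
  # strong tuning is significant; permutation p is small
  set.seed(4)
  tuned <- t(replicate(8, rpois(8, c(20, 6, 2, 1, 1, 1, 2, 6))))
  rest <- direction_selectivity(tuned, dirs, n_perm = 499, seed = 5)
  expect_lt(rest$p_perm, 0.01)
  # ON-OFF index from onset/offset counts
  expect_equal(direction_selectivity(quad, c(0, pi / 2, pi, 3 * pi / 2),
                                     n_perm = 9, onset = 6,
                                     offset = 2)$on_off_index, 0.5)
  expect_error(direction_selectivity(matrix(0, 3, 8), dirs), "all-zero")
})
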