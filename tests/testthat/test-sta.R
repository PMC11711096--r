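test_that("a single spike reproduces the preceding stimulus snippet", {
  stim <- make_checkerboard(30, 7.5, c(6, 6), 20, duration_s = 5, seed = 7)
  counts <- matrix(0L, 1, 100)
  counts[1, 60] <- 1L
  sta <- compute_sta(stim, spike_raster(counts, 1 / 20), window_s = 0.5)
  expect_equal(sta$n_lags, 10)
  for (l in 1:10)
    expect_equal(sta$sta[l, , ], stim$frames[60 - (l - 1), , ])
})

test_that("STA is linear in the spike weights", {
  stim <- make_checkerboard(30, 7.5, c(6, 6), 20, duration_s = 20, seed = 8)
  set.seed(1)
  c1 <- matrix(rpois(400, 0.5), 1)
  c2 <- matrix(rpois(400, 0.8), 1)
  s1 <- compute_sta(stim, spike_raster(c1, 1 / 20))
  s2 <- compute_sta(stim, spike_raster(c2, 1 / 20))
  s12 <- compute_sta(stim, spike_raster(c1 + c2, 1 / 20))
  w1 <- s1$n_spikes; w2 <- s2$n_spikes
  expect_equal(s12$sta, (w1 * s1$sta + w2 * s2$sta) / (w1 + w2))
})

test_that("filter separation recovers a rank-1 STA exactly (up to sign)", {
  set.seed(3)
  spat <- matrix(rnorm(64), 8, 8)
  temp <- c(0.1, 0.8, 0.4, -0.5, -0.2)
  sta <- array(0, dim = c(5, 8, 8))
  for (l in 1:5) sta[l, , ] <- temp[l] * spat
  sep <- separate_filters(sta, threshold = 0.5)
  expect_gt(abs(stats::cor(sep$temporal, temp)), 1 - 1e-10)
  # spatial filter = projection onto the unit temporal filter
  expect_equal(sep$spatial * sign(sum(sep$spatial * spat)) / sqrt(sum(temp^2)),
               spat, tolerance = 1e-8)
  # extremum of the temporal filter is positive by convention
  expect_gt(max(sep$temporal), abs(min(sep$temporal)) - 1e-12)
})

test_that("degenerate robust SD and empty stixel selection are flagged", {
  sta <- array(0, dim = c(4, 3, 3)); sta[2, 2, 2] <- 1
  # robust SD of mostly-zero elements is 0: threshold degenerates
  expect_error(separate_filters(sta), "robust SD")
  sta2 <- array(rnorm(4 * 9, sd = 1), dim = c(4, 3, 3))
  expect_error(separate_filters(sta2, threshold = 100), "no stixel")
})

test_that("planted LN filter is recovered from checkerboard responses", {
  stim <- make_checkerboard(30, 7.5, c(16, 16), 30, duration_s = 330, seed = 4)
  co <- list(x = (1:16 - 8.5) * 30, y = (1:16 - 8.5) * 30)
  xg <- matrix(co$x, 16, 16, byrow = TRUE); yg <- matrix(co$y, 16, 16)
  filt <- exp(-((xg - 20)^2 + (yg + 10)^2) / (2 * 60^2)) -
    0.4 * exp(-((xg - 20)^2 + (yg + 10)^2) / (2 * 120^2))
  filt <- filt / sqrt(sum(filt^2))
  enc <- ln_encoder(filt, temporal_kernel = c(0.1, 0.9, 0.4, -0.3, -0.1),
                    nonlinearity = "softplus", gain = 3, threshold = -1,
                    rate_scale = 30)
  rast <- simulate_responses(population(list(enc)), stim, seed = 5)[[1]]
  expect_gt(sum(rast$counts), 5000)
  sep <- separate_filters(compute_sta(stim, rast))
  cosine <- sum(sep$spatial * filt) /
    sqrt(sum(sep$spatial^2) * sum(filt^2))
  expect_gt(abs(cosine), 0.95)
})

test_that("contours give the closed-form area for a Gaussian filter", {
  co <- list(x = (1:16 - 8.5) * 30, y = (1:16 - 8.5) * 30)
  xg <- matrix(co$x, 16, 16, byrow = TRUE); yg <- matrix(co$y, 16, 16)
  g <- exp(-(xg^2 + yg^2) / (2 * 70^2))
  res <- extract_contour(g, 30, target_pitch = 30 / 16, sigma_blur_px = 4,
                         level = 0.25)
  # 25%-level radius measured from the blurred filter itself: the enclosed
  # area must match the circle area within 2%
  bl <- res$blurred
  peak <- which(bl == max(bl), arr.ind = TRUE)[1, ]
  row <- bl[peak[1], ]
  lev <- 0.25 * max(bl)
  right <- which(row[peak[2]:length(row)] < lev)[1] + peak[2] - 1
  frac <- (row[right - 1] - lev) / (row[right - 1] - row[right])
  r25 <- (right - 1 - peak[2] + frac) * 30 / 16
  expect_lt(abs(res$area / (pi * r25^2) - 1), 0.02)
  # symmetric filter: centre at the peak
  expect_lt(max(abs(res$centre)), 4)
  # contour area is invariant to positive rescaling of the filter
  res2 <- extract_contour(5 * g, 30, target_pitch = 30 / 16)
  expect_equal(res2$area, res$area)
})

test_that("contour outlier triage removes isolated far points", {
  set.seed(8)
  theta <- seq(0, 2 * pi, length.out = 121)[-121]
  r <- 50 + rnorm(120, sd = 2)            # irregular contour radii
  cx <- r * cos(theta); cy <- r * sin(theta)
  cx[40] <- 400; cy[40] <- 400  # one far outlier
  d <- sqrt(diff(cx)^2 + diff(cy)^2)
  rsd <- 1.4826 * stats::median(abs(d - stats::median(d)))
  bad_seg <- d > 20 * rsd
  bad_pt <- c(FALSE, bad_seg) & c(bad_seg, FALSE)
  expect_equal(which(bad_pt), 40)
})

test_that("symmetrized R2 has its fixed points and error cases", {
  x <- rnorm(100)
  expect_equal(symmetrized_r2(x, x), 1)
  set.seed(2)
  a <- rnorm(200); b <- rnorm(200)
  expect_equal(symmetrized_r2(a, b), symmetrized_r2(b, a))
  expect_lt(symmetrized_r2(a, b), 1)  # 1 only for identical traces
  # large independent noise drives it to <= 0.1
  sig <- rnorm(500)
  expect_lt(symmetrized_r2(sig, sig + rnorm(500, sd = 10)), 0.1)
  expect_error(symmetrized_r2(rep(1, 10), rnorm(10)), "zero-variance")
})

test_that("per-fixation Fano factors obey the Poisson and exclusion rules", {
  fix <- data.frame(fixation = 1:4,
                    start_frame = c(1, 26, 51, 76),
                    end_frame = c(26, 51, 76, 101))
  set.seed(9)
  # Poisson counts, mean 8 spikes per fixation -> Fano ~ 1
  counts <- matrix(rpois(200 * 100, 8 / 25), 200, 100)
  res <- fano_per_fixation(spike_raster(counts, 0.01), fix)
  expect_lt(abs(res$fano_weighted - 1), 0.15)
  # deterministic identical trials -> Fano 0
  det <- matrix(rep(rpois(100, 0.5), each = 4), 4, 100)
  res0 <- fano_per_fixation(spike_raster(det, 0.01), fix)
  expect_true(all(res0$per_fixation$fano[res0$per_fixation$included] == 0))
  # a fixation with mean below 3 spikes is excluded from the summary
  low <- counts; low[, 1:25] <- 0L; low[1:70, 1] <- 1L  # mean 0.35 < 3
  resl <- fano_per_fixation(spike_raster(low, 0.01), fix)
  expect_false(resl$per_fixation$included[1])
})
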