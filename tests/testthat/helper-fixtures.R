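# Shared fixtures for the test-suite; everything is generated in code.

# small flashed battery (8 frequencies x 3 orientations x 2 phases)
small_battery <- function(n_trials = 2, seed = 5) {
  half_periods <- exp(seq(log(20), log(600), length.out = 8))
  make_grating_battery(1 / (2 * half_periods), c(0, pi / 3, 2 * pi / 3),
                       c(0, pi / 2), layout = "flashed",
                       n_trials = n_trials, seed = seed)
}

# random valid DoG parameter draw
random_dog <- function() {
  dog_spatial(x0 = stats::runif(1, -100, 100), y0 = stats::runif(1, -100, 100),
              sigma_x = stats::runif(1, 10, 60),
              sigma_y = stats::runif(1, 10, 60),
              theta_dog = stats::runif(1, -pi / 4 + 0.01, pi / 4 - 0.01),
              k_s = stats::runif(1, 1.2, 4),
              w_surr = stats::runif(1, 0, 0.8))
}

random_grating <- function(f_max = 1 / 60) {
  grating_spec(f = stats::runif(1, 0, f_max),
               theta = stats::runif(1, 0, pi),
               phi = stats::runif(1, 0, 2 * pi))
}

# Poisson raster with a given per-bin rate (Hz), bin width bw
poisson_raster <- function(rate_hz, n_trials, bw = 4e-4, seed = 1) {
  counts <- t(vapply(seq_len(n_trials), function(tr) {
    set.seed(seed * 1000 + tr)
    stats::rpois(length(rate_hz), rate_hz * bw)
  }, numeric(length(rate_hz))))
  spike_raster(counts, bw)
}
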