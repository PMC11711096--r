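test_that("the DoG LN likelihood at the truth equals the analytic Poisson NLL", {
  stim <- small_battery(n_trials = 2)
  truth <- dog_spatial(x0 = 10, y0 = 0, sigma_x = 40, sigma_y = 50,
                       theta_dog = 0.1, k_s = 2, w_surr = 0.4)
  enc <- dog_ln_encoder(truth, beta = 3, gamma = -1, a = 4)
  rast <- simulate_responses(population(list(enc)), stim, seed = 3)[[1]]
  counts <- as.numeric(rast$counts)
  par <- c(10, 0, 40, 50, 0.1, 2, 0.4, 3, -1, 4)
  agg <- rgcpop:::aggregate_flash_counts(stim, counts)
  nll <- rgcpop:::dogln_nll(par, agg, "exact")
  rates <- encoder_rate(enc, stim)
  expect_equal(nll, poisson_nll(rates, counts), tolerance = 1e-10)
})

test_that("fit_dog_ln rejects empty data and flags a fit object", {
  stim <- small_battery(n_trials = 1)
  expect_error(fit_dog_ln(stim, rep(0, nrow(stim$schedule))), "no spikes")
})

test_that("sg_predict hits its closed-form corners", {
  grid <- subunit_grid(c(0, 0), n_sites = 19, spacing = 16)
  p0 <- sg_params(grid, w = rep(0, 19), out = list(a = 4, b = 0.7, n = 2, k = 1))
  gr <- small_battery()$gratings
  # all weights zero: output is the Naka-Rushton baseline b
  expect_equal(sg_predict(p0, gr), rep(0.7, nrow(gr)))
  # increasing any single weight never decreases the response
  p1 <- sg_params(grid, w = runif(19, 0, 1), beta = 3, gamma = -1,
                  out = list(a = 4, b = 0.7, n = 2, k = 1))
  r1 <- sg_predict(p1, gr)
  p2 <- p1; p2$w[7] <- p2$w[7] + 0.5
  expect_true(all(sg_predict(p2, gr) >= r1 - 1e-12))
})

test_that("a single subunit in its linear range matches the DoG LN geometry", {
  grid <- matrix(c(5, -3), 1, 2)
  gr <- small_battery()$gratings
  beta <- 1e-4
  p <- sg_params(grid, w = 1, sigma = 20, k_s = 2, w_surr = 0.3,
                 beta = beta, gamma = 0,
                 out = list(a = 1, b = 0, n = 1, k = 1))
  pooled <- logistic(beta * rgcpop:::sg_activations(p, gr) + 0)[, 1]
  lin <- (pooled - 0.5) / (beta / 4)  # small-signal expansion of the logistic
  dog <- dog_grating_response(
    dog_spatial(5, -3, 20, 20, 0, 2, 0.3),
    list(f = gr$f, theta = gr$theta, phi = gr$phi))$response
  expect_equal(lin, dog, tolerance = 1e-6)
})

test_that("the density penalty is symmetric and decreasing in distance", {
  grid <- subunit_grid(c(0, 0), n_sites = 7, spacing = 16)
  w <- runif(7, 0.1, 1)
  pen <- function(grid, w) {
    dinv2 <- 1 / as.matrix(stats::dist(grid / 1000))^2; diag(dinv2) <- 0
    sum(w * (dinv2 %*% w))
  }
  # invariant under relabeling
  perm <- sample(7)
  expect_equal(pen(grid, w), pen(grid[perm, ], w[perm]))
  # strictly decreasing when any pairwise distance grows
  grid2 <- grid; grid2[2, ] <- grid2[2, ] * 3
  expect_lt(pen(grid2, w), pen(grid, w))
})

test_that("the stochastic gradient matches finite differences", {
  set.seed(31)
  stim <- small_battery(n_trials = 1)
  grid <- subunit_grid(c(0, 0), 30, 16)
  ns <- nrow(grid)
  dinv2 <- 1 / as.matrix(stats::dist(grid / 1000))^2; diag(dinv2) <- 0
  agg <- rgcpop:::aggregate_flash_counts(stim, rpois(nrow(stim$schedule), 2))
  cosT <- rgcpop:::sg_cos_theta(grid, agg$gratings)
  theta <- c(runif(ns, 0, 0.5), 14, 2.2, 0.3, 3, -1.5, 4, 0.05, 1.8, 0.9)
  y <- rpois(20, 2); gid <- sample(nrow(agg$gratings), 20, replace = TRUE)
  g <- rgcpop:::sg_batch_grad(theta, ns, gid, y, cosT, agg$gratings$f,
                              2 * pi^2, 0.01, dinv2, 3e-4)
  idx <- c(1, 4, ns + 1:9)
  num <- vapply(idx, function(i) {
    h <- 1e-6 * max(abs(theta[i]), 1)
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    (rgcpop:::sg_batch_grad(tp, ns, gid, y, cosT, agg$gratings$f, 2 * pi^2,
                            0.01, dinv2, 3e-4)$cost -
       rgcpop:::sg_batch_grad(tm, ns, gid, y, cosT, agg$gratings$f, 2 * pi^2,
                              0.01, dinv2, 3e-4)$cost) / (2 * h)
  }, numeric(1))
  expect_equal(g$grad[idx], num, tolerance = 1e-5)
})

test_that("projection enforces every constraint exactly", {
  ns <- 5
  theta <- c(-1, 0.2, -0.3, 2, 1,   # weights (some negative)
             300, 0.5, 1.5, 99, -99, -5, -1, 10, 7)
  pr <- rgcpop:::sg_project(theta, ns)
  expect_true(all(pr[1:5] >= 0))
  expect_true(pr[ns + 1] >= 7.51 && pr[ns + 1] <= 200)
  expect_true(pr[ns + 2] > 1 && pr[ns + 2] < 6)
  expect_true(pr[ns + 3] >= 0 && pr[ns + 3] < 1)
  expect_true(pr[ns + 6] > 0)       # out a
  expect_true(pr[ns + 7] >= 0)      # out b
  expect_true(pr[ns + 8] >= 0.5 && pr[ns + 8] <= 8)
  expect_equal(pr[ns + 9], 1)       # half-saturation pinned
})

test_that("pruning applies the 5% and 2.5-sigma rules", {
  stim <- small_battery(n_trials = 2)
  grid <- rbind(hex_mosaic(1, 32), c(400, 400))  # 7 sites + 1 far outlier
  enc <- sg_encoder(grid[1:7, ], w = rep(1, 7), sigma = 15, beta = 4,
                    gamma = -2, out = list(a = 4, b = 0.1, n = 2, k = 1))
  rast <- simulate_responses(population(list(enc)), stim, seed = 3)[[1]]
  counts <- as.numeric(rast$counts)
  params <- sg_params(grid, w = c(1.0, 0.04, 0.8, rep(0.5, 4), 0.3),
                      sigma = 15, beta = 4, gamma = -2,
                      out = list(a = 4, b = 0.1, n = 2, k = 1))
  fit <- structure(list(params = params, lambda = 0,
                        n_spikes = sum(counts), n_data = length(counts)),
                   class = "sg_fit")
  pruned <- prune_and_refit(fit, stim, counts)
  # weight 0.04 < 5% of max 1.0: zeroed
  expect_equal(pruned$params$w[2], 0)
  # the far site (weight 0.3 > 5%) is removed by the 2.5-sigma rule
  expect_equal(pruned$params$w[8], 0)
  # the others survive (possibly rescaled by a common factor)
  surv <- pruned$params$w[c(1, 3:7)]
  expect_true(all(surv > 0))
  expect_lt(stats::sd(surv / params$w[c(1, 3:7)]), 1e-8)
})

test_that("BIC arithmetic and model selection follow the printed rules", {
  expect_equal(sg_bic(5, 1200, -3000), 5 * log(1200) + 6000)
  mk <- function(lambda, n_sub, cov_spacing, loglik) {
    grid <- subunit_grid(c(0, 0), max(n_sub, 3), cov_spacing)
    w <- c(rep(1, n_sub), rep(0, max(n_sub, 3) - n_sub))
    structure(list(params = sg_params(grid, w, sigma = 4),
                   loglik = loglik, lambda = lambda, n_data = 1200,
                   eligible = TRUE), class = "sg_fit")
  }
  # sigma 4 -> subunit diameter 16; spacing 16 -> coverage 1 (eligible),
  # spacing 4 -> coverage 4 (ineligible)
  cands <- list(mk(1e-6, 2, 16, -100),    # too few subunits
                mk(1e-5, 5, 4, -90),      # coverage too high
                mk(1e-4, 5, 16, -120))
  sel <- select_model(cands)
  expect_equal(sel$fit$lambda, 1e-4)      # only eligible one wins despite BIC
  # exact BIC ties break towards the smaller lambda
  cands2 <- list(mk(1e-5, 5, 16, -100), mk(1e-4, 5, 16, -100))
  expect_equal(select_model(cands2)$fit$lambda, 1e-5)
  # nothing eligible: excluded status
  expect_equal(select_model(list(mk(1e-6, 2, 16, -100)))$status, "excluded")
})

test_that("coverage and nonlinearity asymmetry match their fixtures", {
  grid <- subunit_grid(c(0, 0), 19, 16)
  p <- sg_params(grid, w = rep(1, 19), sigma = 4)
  expect_equal(sg_coverage(p), 1)  # diameter 16 over spacing 16
  p2 <- sg_params(grid, w = c(1, 1, rep(0, 17)), sigma = 4)
  expect_error(sg_coverage(p2), "fewer than three")
  # odd-symmetric nonlinearity: asymmetry 0
  expect_equal(nonlinearity_asymmetry(function(x) x), 0, tolerance = 1e-6)
  # fully rectified: asymmetry 1
  expect_equal(nonlinearity_asymmetry(function(x) pmax(x, 0)), 1)
  # M = 0.5 fixture: asymmetry 1/3
  expect_equal(nonlinearity_asymmetry(function(x) pmax(x, -0.5)), 1 / 3,
               tolerance = 1e-3)
})

test_that("the default epoch schedule follows 4e5 / N_trials", {
  expect_equal(max(1, round(4e5 / 4000)), 100)
  stim <- small_battery(n_trials = 1)
  counts <- rpois(nrow(stim$schedule), 1)
  cfg <- sg_config(n_epochs = 2, n_sites = 40, polish = FALSE, seed = 2)
  f <- fit_sg(stim, counts, config = cfg)
  expect_equal(length(f$cost_trace), 2)
  expect_true(all(is.finite(f$cost_trace)))
})

test_that("training cost decreases over the stochastic fit", {
  stim <- small_battery(n_trials = 3)
  enc <- sg_encoder(hex_mosaic(1, 32), w = rep(1, 7), sigma = 15, beta = 4,
                    gamma = -2, out = list(a = 4, b = 0.1, n = 2, k = 1))
  rast <- simulate_responses(population(list(enc)), stim, seed = 6)[[1]]
  f <- fit_sg(stim, as.numeric(rast$counts),
              config = sg_config(n_epochs = 12, n_sites = 100, seed = 3,
                                 polish = FALSE))
  expect_lt(f$cost_trace[12], f$cost_trace[1])
})
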