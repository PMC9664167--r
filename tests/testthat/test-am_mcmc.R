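make_cfg <- function(series, ...) {
  default_mcmc_config(series, noise_sd = 0.02, seed = 99,
                      chain_length = 5e3, burn_in = 1e3, n_chains = 2, ...)
}

test_that("log-posterior is Gaussian in the residual and -Inf outside support", {
  ds <- generate_dataset(generator_config("lh_like", n_impulses = 3,
                                          noise_sd = 0, seed = 18))
  cfg <- make_cfg(ds$series, n_impulses = 3)
  # the generating parameters reproduce the noise-free data exactly
  p0 <- c(ds$impulses$times, ds$impulses$weights, ds$plant$b1, ds$plant$b2)
  expect_equal(log_posterior(p0, ds$series, cfg), 0)
  # log-density differences are exactly -(RSS1 - RSS2)/(2 sigma^2)
  p1 <- p0; p1[4] <- p1[4] * 1.3
  p2 <- p0; p2[4] <- p2[4] * 0.6
  rss <- function(p) {
    tr <- impulse_train(p[1:3], p[4:6], allow_zero = TRUE)
    pl <- plant_parameters(p[7], p[8])
    sum((ds$series$values - simulate_output(pl, tr, ds$series$times))^2)
  }
  expect_equal(log_posterior(p1, ds$series, cfg) -
               log_posterior(p2, ds$series, cfg),
               -(rss(p1) - rss(p2)) / (2 * cfg$noise_sd^2),
               tolerance = 1e-10)
  # outside the prior box
  pbad <- p0; pbad[1] <- cfg$prior_tau[2] + 1
  expect_identical(log_posterior(pbad, ds$series, cfg), -Inf)
  pbad2 <- p0; pbad2[8] <- pbad2[7] + 0.1   # violates b2 < b1
  expect_identical(log_posterior(pbad2, ds$series, cfg), -Inf)
})

test_that("sampler is deterministic given the seed and respects the support", {
  ds <- lh_dataset(seed = 19, noise_frac = 0.02)
  cfg <- make_cfg(ds$series, chain_length = 2e3, burn_in = 500)
  ch1 <- run_adaptive_metropolis(ds$series, cfg)
  ch2 <- run_adaptive_metropolis(ds$series, cfg)
  expect_identical(ch1[[1]]$samples, ch2[[1]]$samples)
  expect_identical(ch1[[2]]$samples, ch2[[2]]$samples)
  expect_false(identical(ch1[[1]]$samples, ch1[[2]]$samples))
  for (ch in ch1) {
    acc <- mean(ch$accept)
    expect_true(acc > 0 && acc < 1)
    expect_true(all(ch$samples[, "b2"] < ch$samples[, "b1"]))
    expect_true(all(ch$samples[, "b1"] >= cfg$prior_b1[1] &
                    ch$samples[, "b1"] <= cfg$prior_b1[2]))
  }
})

test_that("sampler reproduces a known one-dimensional Gaussian target", {
  # one impulse, all parameters but its weight pinned by narrow priors:
  # the posterior over the weight is a truncated-Gaussian with known
  # mean and sd (effectively untruncated here)
  times <- seq(0, 300, by = 10)
  b1 <- 0.3; b2 <- 0.02; tau <- 40; dtrue <- 2
  z <- kernel_z(b1, b2, times - tau)
  sigma <- 0.05
  set.seed(123)
  y <- dtrue * z + rnorm(length(times), 0, sigma)
  s <- sampled_series(times, pmax(y, 0) + 1e-9)
  mu_post <- sum(s$values * z) / sum(z^2)
  sd_post <- sigma / sqrt(sum(z^2))
  # pinning half-widths: negligible for the likelihood yet wide relative
  # to the proposal jitter, so the pinned coordinates do not throttle the
  # acceptance rate
  eps <- 1e-3
  cfg <- mcmc_config(n_impulses = 1, chain_length = 4e4, burn_in = 1e4,
                     n_chains = 2,
                     prior_tau = c(tau - eps, tau + eps),
                     prior_weight = c(0, 10),
                     prior_b1 = c(b1 - eps, b1 + eps),
                     prior_b2 = c(b2 - eps * b2, b2 + eps * b2),
                     noise_sd = sigma, seed = 5)
  init <- rbind(c(tau, 1.5, b1, b2), c(tau, 2.5, b1, b2))
  ch <- run_adaptive_metropolis(s, cfg, init = init)
  d <- unlist(lapply(ch, function(c) c$samples[-(1:cfg$burn_in), "d1"]))
  n_eff_floor <- 200   # conservative: heavy autocorrelation
  mc_se <- sd_post / sqrt(n_eff_floor)
  expect_lt(abs(mean(d) - mu_post), 3 * mc_se)
  expect_lt(abs(sd(d) - sd_post), 0.25 * sd_post)
})

test_that("post-processing reduces over-parameterised samples to the pulse count", {
  ds <- lh_dataset(seed = 3, noise_frac = 0.01)
  cur_fit <- sparsify_fit(solve_weights(ds$series, 0.46, 0.011))
  cfg <- make_cfg(ds$series, chain_length = 1e4, burn_in = 2e3)
  init <- mcmc_init_from_fit(cur_fit$impulses, 0.46, 0.011, cfg)
  ch <- run_adaptive_metropolis(ds$series, cfg, init = init)
  red <- postprocess_chains(ch, thin = 20)
  expect_s3_class(red, "reduced_chains")
  expect_equal(red$target_count, 3)
  expect_equal(ncol(red$chains[[1]]), 2 * 3 + 2)
  expect_true(all(red$flagged >= 0 & red$flagged <= 1))
  # reduced times sorted within each sample
  m <- red$chains[[1]]
  expect_true(all(m[, "tau1"] <= m[, "tau2"] & m[, "tau2"] <= m[, "tau3"]))
})

test_that("merging inside post-processing barely changes the fitted output", {
  b1 <- 0.4; b2 <- 0.012
  times <- seq(0, 500, by = 10)
  pl <- plant_parameters(b1, b2)
  tr <- impulse_train(c(100, 112, 300), c(1, 0.8, 1.2))
  merged <- merge_adjacent(tr, b1, b2, max_gap = 15)
  expect_length(merged$times, 2)
  after <- times[times >= 112]
  ymax <- max(simulate_output(pl, tr, times))
  expect_lt(max(abs(simulate_output(pl, tr, after) -
                    simulate_output(pl, merged, after))), 1e-6 * ymax)
})

test_that("Gelman-Rubin statistic behaves at its analytic anchors", {
  set.seed(77)
  base <- matrix(rnorm(4000), ncol = 2, dimnames = list(NULL, c("a", "b")))
  # identical chains: R-hat exactly 1
  # identical chains: B = 0, R-hat = sqrt((n-1)/n), i.e. 1 up to O(1/n)
  gr_same <- gelman_rubin(list(base, base, base))
  expect_equal(unname(gr_same$rhat), c(1, 1), tolerance = 1e-3)
  expect_true(gr_same$converged)
  # independent draws from one distribution: R-hat near 1
  ind <- lapply(1:4, function(i) matrix(rnorm(8000), ncol = 2,
                                        dimnames = list(NULL, c("a", "b"))))
  expect_lt(max(gelman_rubin(ind)$rhat), 1.01)
  # disjoint means dominated by between-chain variance: R-hat large
  sep <- list(base, base + 10)
  expect_gt(min(gelman_rubin(sep)$rhat), 2)
  expect_false(gelman_rubin(sep)$converged)
  # zero within-chain variance is reported as undefined
  flat <- lapply(1:2, function(i) matrix(1, 100, 1, dimnames = list(NULL, "c")))
  expect_true(is.na(gelman_rubin(flat)$rhat))
})

test_that("curve distances carry the adopted sign convention and quantile geometry", {
  pts <- data.frame(b1 = seq(0.2, 0.6, by = 0.1),
                    b2_tilde = rep(0.01, 5), b2_hat = rep(0.01, 5),
                    residual = 0, n_impulses = 3, discontinuity = FALSE)
  cur <- structure(list(points = pts, impulses = list(), config = NULL),
                   class = "gamma_curve")
  # exactly on the curve
  on <- curve_distance_stats(cbind(b1 = 0.4, b2 = 0.01), cur)
  expect_equal(on$signed_dist, 0)
  # above the curve (faster b2): inside the fast region, negative
  above <- curve_distance_stats(cbind(b1 = 0.4, b2 = 0.02), cur)
  expect_equal(above$signed_dist, -0.01)
  below <- curve_distance_stats(cbind(b1 = 0.4, b2 = 0.004), cur)
  expect_equal(below$signed_dist, 0.006)
  # equal-tailed interval equals independently computed quantiles on a
  # symmetric synthetic distance sample
  set.seed(42)
  b2s <- 0.01 + rnorm(4000, 0, 0.002)
  cd <- curve_distance_stats(cbind(b1 = runif(4000, 0.25, 0.55), b2 = b2s),
                             cur, levels = 0.5)
  qs <- quantile(cd$signed_dist, c(0.25, 0.75), names = FALSE)
  expect_equal(cd$intervals$perp_lo, qs[1])
  expect_equal(cd$intervals$perp_hi, qs[2])
  # along-curve interval: flat horizontal curve, arc quantiles map to
  # b1 positions; length is the Euclidean distance between the end-points
  aq <- quantile(cd$arc, c(0.25, 0.75), names = FALSE)
  expect_equal(cd$intervals$along_length, diff(aq), tolerance = 1e-6)
  expect_error(curve_distance_stats(matrix(numeric(0), 0, 2), cur), "empty")
})
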