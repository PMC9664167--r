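test_that("design matrix has the decay column and causal kernel structure", {
  times <- seq(0, 50, by = 10)
  K <- length(times)
  Phi <- build_design_matrix(0.3, 0.04, times)
  expect_equal(dim(Phi), c(K, K))
  expect_equal(Phi[, 1], exp(-0.04 * times))
  expect_true(all(Phi[, 1] > 0))
  # impulse block strictly lower triangular: entries vanish for t_i <= t_j
  for (j in 2:K) expect_true(all(Phi[seq_len(j - 1), j] == 0))
  expect_true(all(is.finite(Phi)) && all(Phi >= 0))
  expect_error(build_design_matrix(0.3, 0.04, c(10, 0, 20)), "increasing")
})

test_that("design-matrix product reproduces the forward model", {
  times <- seq(0, 200, by = 10)
  K <- length(times)
  b1 <- 0.35; b2 <- 0.02
  theta <- numeric(K)
  theta[1] <- 0.8                        # x2(t1)
  theta[c(3, 9)] <- c(1.2, 0.5)          # impulses at t_2 and t_8
  pl <- plant_parameters(b1, b2, x2_init = 0.8)
  tr <- impulse_train(times[c(2, 8)], c(1.2, 0.5))
  y <- simulate_output(pl, tr, times)
  expect_equal(drop(build_design_matrix(b1, b2, times) %*% theta), y,
               tolerance = 1e-12)
  # K = 2, decay only
  Phi2 <- build_design_matrix(b1, b2, c(0, 15))
  expect_equal(drop(Phi2 %*% c(3, 0)), c(3, 3 * exp(-b2 * 15)),
               tolerance = 1e-14)
})

test_that("non-negative solver returns the exact constrained minimiser", {
  # zero data -> zero solution
  s0 <- sampled_series(seq(0, 40, by = 10), rep(0, 5))
  f0 <- solve_weights(s0, 0.3, 0.05)
  expect_equal(f0$theta, rep(0, 5))
  expect_equal(f0$residual, 0)

  # noise-free simulate-then-fit at the generating parameters
  ds <- generate_dataset(generator_config("lh_like", n_impulses = 3,
                                          noise_sd = 0, seed = 2))
  fit <- solve_weights(ds$series, ds$plant$b1, ds$plant$b2)
  yss <- sum(ds$series$values^2)
  expect_lt(fit$residual, 1e-16 * yss)
  est <- fit_impulses(fit, min_weight = 1e-8)
  expect_equal(est$times, ds$impulses$times)
  expect_equal(est$weights, ds$impulses$weights, tolerance = 1e-6)
})

test_that("solver agrees with brute-force active-set enumeration on small problems", {
  set.seed(7)
  for (i in 1:25) {
    K <- sample(3:6, 1)
    times <- cumsum(runif(K, 5, 15))
    s <- sampled_series(times, abs(rnorm(K, 1, 1)))
    b1 <- runif(1, 0.1, 0.6); b2 <- runif(1, 0.01, 0.09)
    fit <- solve_weights(s, b1, b2)
    oracle <- nnls_enumerate(build_design_matrix(b1, b2, times), s$values)
    expect_equal(fit$residual, oracle$rss, tolerance = 1e-8)
    expect_equal(fit$theta, oracle$x, tolerance = 1e-6)
  }
})

test_that("solver matches an independent active-set implementation", {
  set.seed(11)
  for (i in 1:10) {
    K <- sample(8:20, 1)
    times <- seq(0, by = 10, length.out = K)
    s <- sampled_series(times, abs(rnorm(K, 1, 1)))
    b1 <- runif(1, 0.1, 0.6); b2 <- runif(1, 0.01, 0.09)
    fit <- solve_weights(s, b1, b2)
    ref <- pracma::lsqnonneg(build_design_matrix(b1, b2, times), s$values)
    expect_equal(fit$theta, ref$x, tolerance = 1e-6)
  }
})

test_that("fast dynamics achieve a near-perfect fit to arbitrary positive data", {
  set.seed(5)
  times <- seq(0, 300, by = 10)
  s <- sampled_series(times, runif(length(times), 0.5, 3))
  fit <- solve_weights(s, 10, 5)
  expect_lt(fit$residual, 1e-8 * sum(s$values^2))
  expect_true(all(fit$theta >= 0))
})

test_that("residual loss rises when rates drop below the generating values", {
  ds <- generate_dataset(generator_config("lh_like", n_impulses = 3,
                                          noise_sd = 0, seed = 4))
  b1 <- ds$plant$b1; b2 <- ds$plant$b2
  expect_lt(residual_loss(ds$series, b1, b2), 1e-16 * sum(ds$series$values^2))
  expect_gt(residual_loss(ds$series, b1, b2 * 0.8), 1e-6)
  expect_gt(residual_loss(ds$series, b1 * 0.7, b2 * 0.9), 1e-6)
  # g weakly decreasing in b2 below the boundary at fixed b1
  g <- vapply(seq(0.5, 1, length.out = 8) * b2,
              function(b) residual_loss(ds$series, b1, b), numeric(1))
  expect_true(all(diff(g) <= 1e-10))
})

test_that("pinning entries to zero never lowers the achievable fit", {
  set.seed(9)
  ds <- generate_dataset(generator_config("lh_like", n_impulses = 4,
                                          noise_sd = 0.05, seed = 9))
  fit <- solve_weights(ds$series, 0.4, 0.012)
  for (i in 1:5) {
    zero <- sample(which(fit$theta > 0), 2)
    refit <- solve_weights(ds$series, 0.4, 0.012, fixed_zero = zero)
    expect_gte(refit$residual + 1e-12, fit$residual)
    expect_true(all(refit$theta[zero] == 0))
  }
})
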