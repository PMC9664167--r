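# Shared fixtures: small deterministic datasets built in code.

# LH-like synthetic dataset with noise expressed as a fraction of the
# clean peak (two-pass generation: the impulse draw is identical because
# it precedes the noise draw in the generator's RNG stream).
lh_dataset <- function(seed, n_impulses = 3, noise_frac = 0.01, ...) {
  cfg0 <- generator_config("lh_like", n_impulses = n_impulses,
                           noise_sd = 0, seed = seed, ...)
  peak <- max(generate_dataset(cfg0)$clean)
  generate_dataset(generator_config("lh_like", n_impulses = n_impulses,
                                    noise_sd = noise_frac * peak,
                                    seed = seed, ...))
}

# Tiny series for exactness checks
tiny_series <- function(K = 5, dt = 10, b1 = 0.4, b2 = 0.05,
                        impulses = impulse_train(10, 1), x2 = 0.5) {
  times <- seq(0, by = dt, length.out = K)
  pl <- plant_parameters(b1, b2, x2_init = x2)
  sampled_series(times, simulate_output(pl, impulses, times))
}

# Brute-force oracle for non-negative least squares on small problems:
# enumerate every support, solve the unconstrained LS on it, keep the
# best feasible (elementwise non-negative) candidate.
nnls_enumerate <- function(A, b) {
  n <- ncol(A)
  best <- list(x = rep(0, n), rss = sum(b^2))
  for (mask in seq_len(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    x <- tryCatch(qr.solve(A[, S, drop = FALSE], b), error = function(e) NULL)
    if (is.null(x) || any(!is.finite(x)) || any(x < 0)) next
    r <- b - A[, S, drop = FALSE] %*% x
    rss <- sum(r^2)
    if (rss < best$rss - 1e-12) {
      full <- rep(0, n)
      full[S] <- x
      best <- list(x = full, rss = rss)
    }
  }
  best
}
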