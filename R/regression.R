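#' Design matrix of the discretised impulse regression
#'
#' For candidate rates (b1, b2) and sampling times t_1 < ... < t_K, builds
#' the K x K matrix whose i-th row is
#' \deqn{[e^{-b_2 (t_i - t_1)},\; z(b_1,b_2,t_i-t_1),\; \dots,\; z(b_1,b_2,t_i-t_{K-1})].}
#' Column 1 carries the decay of the initial observed concentration; column
#' j+1 carries a candidate impulse anchored at sampling time t_j. Causality
#' makes the impulse block strictly lower triangular: an impulse at t_j
#' first influences samples at t_i > t_j.
#'
#' @param b1,b2 Positive candidate elimination rates, 1/min.
#' @param times Strictly increasing sampling times, min.
#' @return K x K numeric matrix, entries finite and >= 0.
#' @export
build_design_matrix <- function(b1, b2, times) {
  stopifnot(is.numeric(times), length(times) >= 2L, all(is.finite(times)))
  if (any(diff(times) <= 0))
    stop("sampling times must be strictly increasing", call. = FALSE)
  if (b1 <= 0 || b2 <= 0)
    stop("elimination rates must be positive", call. = FALSE)
  K <- length(times)
  dt <- outer(times, times[-K], "-")
  cbind(exp(-b2 * (times - times[1L])),
        matrix(kernel_z(b1, b2, dt), nrow = K, ncol = K - 1L),
        deparse.level = 0)
}

#' Non-negative least-squares fit of the discretised impulse model
#'
#' Solves the inner estimation problem at fixed candidate rates:
#' \deqn{\hat\theta(b_1,b_2) = \arg\min_{\theta \ge 0} \|Y - \Phi(b_1,b_2)\theta\|^2,}
#' with \eqn{\theta = [x_2(t_1), d_1, \dots, d_{K-1}]}. The initial
#' concentration is part of the non-negativity constraint (a concentration
#' cannot be negative); a nonzero upstream initial state is equivalently
#' represented by the candidate impulse at t_1. Solved with a
#' Lawson-Hanson active-set routine, so the returned active set is exact
#' and reproducible.
#'
#' @param series A [sampled_series()] object.
#' @param b1,b2 Positive candidate elimination rates, 1/min.
#' @param fixed_zero Optional integer indices (into theta, 1 = x2(t1),
#'   j+1 = impulse at t_j) constrained to exactly zero, used by the
#'   sparsification refit.
#' @param warm Optional integer theta indices used to warm-start the
#'   active-set solver (typically the support of a fit at a nearby
#'   parameter pair); the solution is unaffected, only the iteration
#'   count.
#' @return An object of class `regression_fit`: list with `theta`
#'   (length K, >= 0), `residual` (squared-error loss g), `fitted`,
#'   `b1`, `b2`, `series`, and `support` (indices of nonzero theta
#'   entries).
#' @seealso [residual_loss()], [threshold_and_refit()]
#' @export
solve_weights <- function(series, b1, b2, fixed_zero = integer(0),
                          warm = NULL) {
  stopifnot(inherits(series, "sampled_series"))
  K <- length(series$times)
  Phi <- build_design_matrix(b1, b2, series$times)
  free <- setdiff(seq_len(K), as.integer(fixed_zero))
  if (length(free) == 0L)
    stop("cannot constrain every parameter to zero", call. = FALSE)
  warm0 <- if (is.null(warm)) NULL else match(intersect(warm, free), free) - 1L
  sol <- nnls_lh(Phi[, free, drop = FALSE], series$values, warm = warm0)
  theta <- numeric(K)
  theta[free] <- sol$x
  fitted <- drop(Phi %*% theta)
  if (any(!is.finite(theta)))
    stop("non-negative least-squares solver returned non-finite weights at (",
         b1, ", ", b2, ")", call. = FALSE)
  structure(list(theta = theta,
                 residual = sum((series$values - fitted)^2),
                 fitted = fitted,
                 b1 = b1, b2 = b2,
                 series = series,
                 support = which(theta > 0),
                 fixed_zero = as.integer(fixed_zero)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("Impulse regression fit at (b1, b2) = (%.5g, %.5g)\n",
              x$b1, x$b2))
  cat(sprintf("  residual loss g = %.6g, x2(t1) = %.4g, %d nonzero impulses\n",
              x$residual, x$theta[1L], sum(x$theta[-1L] > 0)))
  invisible(x)
}

#' Extract the nonzero impulses of a regression fit
#'
#' Candidate impulse j of the discretised regression is anchored at
#' sampling time t_j; entries with zero solved weight are dropped.
#'
#' @param fit A `regression_fit` from [solve_weights()].
#' @param min_weight Drop weights at or below this value (default 0).
#' @return An [impulse_train()].
#' @export
fit_impulses <- function(fit, min_weight = 0) {
  stopifnot(inherits(fit, "regression_fit"))
  d <- fit$theta[-1L]
  keep <- which(d > min_weight)
  impulse_train(fit$series$times[keep], d[keep])
}

#' Residual loss of the non-negative impulse regression
#'
#' Convenience wrapper returning only
#' \eqn{g(b_1,b_2) = \|Y - \Phi(b_1,b_2)\hat\theta(b_1,b_2)\|^2}, the
#' quantity whose dependence on b2 drives the curve estimator.
#'
#' @inheritParams solve_weights
#' @return Non-negative scalar loss (concentration^2 units).
#' @export
residual_loss <- function(series, b1, b2) {
  solve_weights(series, b1, b2)$residual
}
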