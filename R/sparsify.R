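#' Sparsification settings
#'
#' Controls the post-solution cleanup of a discretised impulse fit:
#' impulses with weight below `d_min` are removed and the remaining ones
#' refit, then surviving impulses at (near-)consecutive candidate positions
#' are merged. `d_min` is expressed as a fraction of the maximal estimated
#' weight when `relative = TRUE` (the practical guidance is a few percent;
#' smaller values suit lower noise, since small impulses are then less
#' likely to be noise artefacts).
#'
#' @param d_min Weight threshold; fraction of the maximal solved weight if
#'   `relative = TRUE` (default 0.02), otherwise absolute.
#' @param relative Interpret `d_min` relative to the maximal weight.
#' @param merge_gap Maximal separation, in candidate-grid positions, for
#'   two impulses to count as adjacent and be merged (default 1).
#' @return An object of class `sparsify_config`.
#' @export
sparsify_config <- function(d_min = 0.02, relative = TRUE, merge_gap = 1L) {
  stopifnot(is.numeric(d_min), length(d_min) == 1L, d_min > 0,
            isTRUE(relative) || isFALSE(relative),
            is.numeric(merge_gap), merge_gap >= 1)
  structure(list(d_min = d_min, relative = relative,
                 merge_gap = as.integer(merge_gap)),
            class = "sparsify_config")
}

#' Threshold small impulses and refit with them pinned to zero
#'
#' Removes impulses whose solved weight falls below the threshold and
#' re-solves the non-negative regression with those entries constrained to
#' exactly zero. Enlarging the zero set can only increase the residual, so
#' the refit loss is always >= the original loss.
#'
#' @param fit A `regression_fit` from [solve_weights()].
#' @param config A [sparsify_config()].
#' @return A `regression_fit` whose thresholded entries are exactly zero.
#'   If every impulse falls below the threshold a decay-only fit (only
#'   x2(t1) free) is returned with a warning.
#' @export
threshold_and_refit <- function(fit, config = sparsify_config()) {
  stopifnot(inherits(fit, "regression_fit"),
            inherits(config, "sparsify_config"))
  d <- fit$theta[-1L]
  thr <- if (config$relative) config$d_min * max(d, 0) else config$d_min
  S <- which(d < thr & d > 0)          # small but nonzero impulses
  zero_idx <- union(fit$fixed_zero, S + 1L)
  if (all(d < thr)) {
    warning("all impulse weights below d_min; returning decay-only fit",
            call. = FALSE)
    zero_idx <- seq_len(length(fit$theta))[-1L]
  }
  if (length(S) == 0L && length(zero_idx) == length(fit$fixed_zero))
    return(fit)
  solve_weights(fit$series, fit$b1, fit$b2, fixed_zero = zero_idx)
}

# Moment-matched replacement of two impulses by one: matches both
# exponential-mode coefficients sum(d e^{b tau}) for b in {b1, b2}, so the
# simulated output at every time at or after the later impulse is unchanged.
# Log-domain arithmetic guards against overflow of e^{b tau}.
merge_pair <- function(tau_a, d_a, tau_b, d_b, b1, b2) {
  if (d_a <= 0) return(c(tau_b, d_b))
  if (d_b <= 0) return(c(tau_a, d_a))
  lse <- function(la, lb) {
    m <- max(la, lb)
    m + log(exp(la - m) + exp(lb - m))
  }
  ls1 <- lse(b1 * tau_a + log(d_a), b1 * tau_b + log(d_b))
  ls2 <- lse(b2 * tau_a + log(d_a), b2 * tau_b + log(d_b))
  tau <- (ls2 - ls1) / (b2 - b1)
  d <- exp(ls2 - b2 * tau)
  stopifnot(tau >= tau_a - 1e-9, tau <= tau_b + 1e-9, d > 0)
  c(tau, d)
}

#' Merge adjacent impulses with no effect on later output
#'
#' Replaces each selected adjacent pair of impulses by a single impulse
#' whose two exponential-mode coefficients match the pair's sums exactly:
#' \deqn{d e^{b \tau} = d_a e^{b \tau_a} + d_b e^{b \tau_b}, \quad b \in \{b_1, b_2\},}
#' which leaves the simulated output unchanged (to machine precision) at
#' every time at or after the later impulse of the pair. The merged time
#' always lies between the pair's times and the merged weight is positive;
#' total modal mass in each mode is conserved exactly. Merging proceeds
#' left to right and is repeated until no adjacent pair remains.
#'
#' @param impulses An [impulse_train()].
#' @param b1,b2 Positive elimination rates with b1 != b2, 1/min.
#' @param max_gap Maximal time separation (min) for two impulses to count
#'   as adjacent.
#' @return An [impulse_train()] with at most as many impulses.
#' @export
merge_adjacent <- function(impulses, b1, b2, max_gap) {
  stopifnot(inherits(impulses, "impulse_train"),
            b1 > 0, b2 > 0,
            is.numeric(max_gap), length(max_gap) == 1L, max_gap > 0)
  if (abs(b1 - b2) / max(b1, b2) < 1e-10)
    stop("merge formula requires distinct elimination rates", call. = FALSE)
  tau <- impulses$times
  d <- impulses$weights
  repeat {
    n <- length(tau)
    if (n < 2L) break
    gaps <- diff(tau)
    i <- which(gaps <= max_gap)
    if (length(i) == 0L) break
    i <- i[1L]
    m <- merge_pair(tau[i], d[i], tau[i + 1L], d[i + 1L], b1, b2)
    tau <- c(tau[seq_len(i - 1L)], m[1L], tau[-seq_len(i + 1L)])
    d <- c(d[seq_len(i - 1L)], m[2L], d[-seq_len(i + 1L)])
  }
  impulse_train(tau, d)
}

#' Full sparsification of a discretised impulse fit
#'
#' Applies [threshold_and_refit()] repeatedly until no nonzero weight
#' remains below the threshold (a constrained refit can raise previously
#' negligible weights above zero, so a single pass need not reach a
#' sub-threshold-free state), then [merge_adjacent()] with the adjacency
#' gap taken as `merge_gap` candidate-grid steps (converted to time using
#' the median sampling interval).
#'
#' @param fit A `regression_fit`.
#' @param config A [sparsify_config()].
#' @return List with the refit (`fit`) and the merged impulse train
#'   (`impulses`).
#' @export
sparsify_fit <- function(fit, config = sparsify_config()) {
  refit <- threshold_and_refit(fit, config)
  for (i in 1:25) {
    again <- threshold_and_refit(refit, config)
    if (identical(again$fixed_zero, refit$fixed_zero)) break
    refit <- again
  }
  imp <- fit_impulses(refit)
  gap <- config$merge_gap * median(diff(fit$series$times)) * (1 + 1e-9)
  if (length(imp) >= 2L)
    imp <- merge_adjacent(imp, fit$b1, fit$b2, max_gap = gap)
  list(fit = refit, impulses = imp)
}
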