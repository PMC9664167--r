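#' Curve-estimation settings
#'
#' Configuration of the outer-level optimisation that traces the estimated
#' feasibility-boundary curve in the (b1, b2) plane. For each value on
#' `b1_grid` the inner problem is solved by gridding b2 on `n_b2`
#' log-spaced points between `b2_min` and just below b1 (the search is
#' restricted to b2 < b1, which pins down the otherwise symmetric labelling
#' of the fast and slow rates). The impulse-count constraint admits at most
#' `Pi` impulses larger than `d_Pi` (a fraction of the maximal solved
#' weight), which excludes the fast-dynamics region where redundant
#' impulses fit any data perfectly.
#'
#' @param b1_grid Strictly increasing positive grid of b1 values, 1/min.
#' @param b2_min Lower end of the b2 search, 1/min. The upper end is
#'   b1 at each grid point.
#' @param n_b2 Number of log-spaced b2 candidates (default 200).
#' @param Pi Maximal number of "large" impulses admitted by the inner
#'   constraint.
#' @param d_Pi Largeness threshold as a fraction of the maximal solved
#'   weight (default 0.05).
#' @param derivative_step Relative central finite-difference step for
#'   d g / d b2 in the Newton-step refinement (default 1e-3).
#' @param sparsify A [sparsify_config()] applied to the per-point impulse
#'   estimate.
#' @return An object of class `curve_config`.
#' @export
curve_config <- function(b1_grid, b2_min, n_b2 = 200L, Pi, d_Pi = 0.05,
                         derivative_step = 1e-3,
                         sparsify = sparsify_config()) {
  stopifnot(is.numeric(b1_grid), length(b1_grid) >= 1L, all(b1_grid > 0),
            all(diff(b1_grid) > 0) || length(b1_grid) == 1L,
            is.numeric(b2_min), length(b2_min) == 1L, b2_min > 0,
            b2_min < max(b1_grid),
            n_b2 >= 10L,
            is.numeric(Pi), Pi >= 1,
            is.numeric(d_Pi), d_Pi > 0,
            derivative_step > 0,
            inherits(sparsify, "sparsify_config"))
  structure(list(b1_grid = as.numeric(b1_grid), b2_min = b2_min,
                 n_b2 = as.integer(n_b2), Pi = as.integer(Pi), d_Pi = d_Pi,
                 derivative_step = derivative_step, sparsify = sparsify),
            class = "curve_config")
}

#' Default curve configuration for a preprocessed series
#'
#' Supplies field-informed defaults: `Pi` is the expected pulse count for
#' the record length at one pulse per 90 min (the physiological LH/GnRH
#' episode spacing in adult males), and the b2 search starts a factor 3
#' below `b2_expected[1]`.
#'
#' @param series A [sampled_series()].
#' @param b1_range Range of b1 to grid over (default the theoretical GnRH
#'   elimination range 0.23-0.69 /min).
#' @param n_b1 Number of b1 grid points (default 24).
#' @param b2_expected Expected range of b2 (default the theoretical LH
#'   elimination range 0.0087-0.014 /min).
#' @param ... Overrides passed on to [curve_config()].
#' @return An object of class `curve_config`.
#' @export
default_curve_config <- function(series, b1_range = c(0.23, 0.69),
                                 n_b1 = 24L,
                                 b2_expected = c(0.0087, 0.014), ...) {
  stopifnot(inherits(series, "sampled_series"))
  span <- diff(range(series$times))
  args <- list(b1_grid = seq(b1_range[1L], b1_range[2L], length.out = n_b1),
               b2_min = b2_expected[1L] / 3,
               Pi = max(1L, ceiling(span / 90)))
  user <- list(...)
  args[names(user)] <- user
  do.call(curve_config, args)
}

#' Newton-step functional of the residual loss
#'
#' \deqn{N_g(b_1, b_2) = -\,g(b_1,b_2) \big/ \,\partial g(b_1,b_2)/\partial b_2,}
#' the step length of Newton's root-finding method applied to g as a
#' function of b2. The partial derivative is computed by central finite
#' differences with relative step `step`. N_g is positive where g decreases
#' in b2, and is invariant to rescaling g. When the derivative magnitude
#' falls below machine tolerance the functional is undefined and `NA` is
#' returned (such candidates are excluded from the inner search).
#'
#' @inheritParams solve_weights
#' @param step Relative central finite-difference step (default 1e-3).
#' @return N_g value (rate units), or `NA` where undefined.
#' @export
newton_functional <- function(series, b1, b2, step = 1e-3) {
  h <- step * b2
  g0 <- residual_loss(series, b1, b2)
  gp <- residual_loss(series, b1, b2 + h)
  gm <- residual_loss(series, b1, b2 - h)
  dg <- (gp - gm) / (2 * h)
  if (!is.finite(dg) || abs(dg) < 1e3 * .Machine$double.eps * max(g0 / b2, 1e-300))
    return(NA_real_)
  -g0 / dg
}

#' Tangent construction for minimising a quadratic-like scalar function
#'
#' For \eqn{f(x) = c_1 (x - x^*)^2 + c_2} with positive constants, the
#' Newton-step functional \eqn{N_f = -f/f'} attains its (positive) minimum
#' \eqn{\sqrt{c_2/c_1}} at \eqn{\tilde x = x^* - \sqrt{c_2/c_1}}, and
#' \eqn{\hat x = \tilde x + N_f(\tilde x) = x^*} exactly: the minimiser is
#' recovered from evaluations left of the minimum only, by intersecting the
#' tangent at \eqn{f(\tilde x)} with the abscissa. This function performs
#' the construction numerically on an arbitrary scalar function over
#' `search = c(lo, hi)`; central differences are exact for quadratics, so
#' the construction is exact (up to optimiser tolerance) whenever `f` is.
#'
#' @param f Scalar function, positive on the search interval.
#' @param search Length-2 numeric search interval for the minimiser of N_f.
#' @param step Absolute central finite-difference step for f' (default
#'   1e-5 of the interval width).
#' @param tol Convergence tolerance of the one-dimensional optimiser.
#' @return List with `x_tilde` (argmin of N_f), `N_min` (min of N_f, must
#'   be positive) and `x_hat = x_tilde + N_min`, the estimated minimiser
#'   of f.
#' @examples
#' tangent_minimizer(function(x) x^2 + 1, c(-5, -1e-3))  # x_hat = 0
#' @export
tangent_minimizer <- function(f, search, step = NULL, tol = 1e-10) {
  stopifnot(is.function(f), is.numeric(search), length(search) == 2L,
            search[1L] < search[2L])
  if (is.null(step)) step <- 1e-5 * diff(search)
  Nf <- function(x) {
    fx <- f(x)
    dfx <- (f(x + step) - f(x - step)) / (2 * step)
    -fx / dfx
  }
  opt <- optimize(Nf, interval = search, tol = tol)
  if (!is.finite(opt$objective) || opt$objective <= 0)
    stop("tangent construction requires min N_f > 0 on the search interval",
         call. = FALSE)
  # Polish the argmin by solving N_f'(x) = 0: an argmin offset propagates
  # into x_hat at first order, so the bracketing optimiser's resolution is
  # sharpened here. N_f' = -1 + f f''/f'^2 uses central differences whose
  # step is tied to min N_f (the distance-to-vertex scale for a
  # quadratic), which keeps the second difference clear of cancellation.
  x <- opt$minimum
  h <- 1e-3 * max(opt$objective, 1e-9 * diff(search))
  Np <- function(x) {
    fp <- (f(x + h) - f(x - h)) / (2 * h)
    fpp <- (f(x + h) - 2 * f(x) + f(x - h)) / h^2
    -1 + f(x) * fpp / fp^2
  }
  lo <- max(search[1L], x - 64 * h)
  hi <- min(search[2L], x + 64 * h)
  n_lo <- Np(lo); n_hi <- Np(hi)
  if (is.finite(n_lo) && is.finite(n_hi) && n_lo < 0 && n_hi > 0) {
    root <- tryCatch(
      uniroot(Np, c(lo, hi), f.lower = n_lo, f.upper = n_hi,
              tol = 1e-13 * max(1, abs(x)))$root,
      error = function(e) NULL)
    if (!is.null(root)) x <- root
  }
  Nmin <- Nf(x)
  if (!is.finite(Nmin) || Nmin <= 0 ||
      Nmin > opt$objective * (1 + 1e-6)) {
    x <- opt$minimum
    Nmin <- opt$objective
  }
  list(x_tilde = x, N_min = Nmin, x_hat = x + Nmin)
}

# Inner sweep over the b2 grid at fixed b1: residual loss, impulse-count
# feasibility, and a grid-difference estimate of N_g used to locate the
# argmin (the Newton step itself is then refined with the configured
# finite-difference stencil).
b2_sweep <- function(series, b1, config) {
  hi <- b1 * (1 - 1e-6)
  if (config$b2_min >= hi) return(NULL)
  grid <- exp(seq(log(config$b2_min), log(hi), length.out = config$n_b2))
  g <- numeric(length(grid))
  feasible <- logical(length(grid))
  supp <- NULL                     # warm-start support carried along the sweep
  for (i in seq_along(grid)) {
    fit <- solve_weights(series, b1, grid[i], warm = supp)
    supp <- fit$support
    g[i] <- fit$residual
    d <- fit$theta[-1L]
    dmax <- max(d, 0)
    feasible[i] <- dmax > 0 && sum(d > config$d_Pi * dmax) <= config$Pi
  }
  # perfect-fit guard: where g is at numerical zero relative to the data
  # the boundary has been reached and the Newton-step functional is
  # undefined (both g and its derivative are roundoff chatter)
  feasible <- feasible & g > 1e-10 * sum(series$values^2)
  dg <- rep(NA_real_, length(grid))
  idx <- 2:(length(grid) - 1L)
  dg[idx] <- (g[idx + 1L] - g[idx - 1L]) / (grid[idx + 1L] - grid[idx - 1L])
  N <- ifelse(is.finite(dg) & dg < 0, -g / dg, NA_real_)
  list(grid = grid, g = g, feasible = feasible, N = N)
}

#' Estimate the slow elimination rate at a fixed fast rate
#'
#' Solves the inner problem of the curve estimator at fixed b1: finds
#' \eqn{\tilde b_2(b_1)}, the minimiser of the Newton-step functional N_g
#' over the b2 grid among candidates whose non-negative fit has at most
#' `Pi` weights above the largeness threshold, then takes the Newton step
#' \eqn{\hat b_2(b_1) = \tilde b_2 + N_g(b_1, \tilde b_2)} (tangent
#' construction). Ties in the argmin resolve to the smallest b2. Setting
#' `Pi >= K` deactivates the impulse-count constraint.
#'
#' @param series A [sampled_series()], preprocessed (basal-subtracted).
#' @param b1 Fixed fast elimination rate, 1/min.
#' @param config A [curve_config()].
#' @return List with `b2_tilde`, `b2_hat` (both positive, `b2_hat >=
#'   b2_tilde`), `N` (the Newton step) and `residual` (loss at b2_tilde),
#'   or `NULL` when no feasible candidate with a positive Newton step
#'   exists at this b1.
#' @export
estimate_b2_at <- function(series, b1, config) {
  stopifnot(inherits(series, "sampled_series"),
            inherits(config, "curve_config"), b1 > 0)
  sw <- b2_sweep(series, b1, config)
  if (is.null(sw)) return(NULL)
  ok <- which(sw$feasible & is.finite(sw$N) & sw$N > 0)
  if (length(ok) == 0L) return(NULL)
  i <- ok[which.min(sw$N[ok])]     # which.min takes the first (smallest b2) tie
  b2_tilde <- sw$grid[i]
  # Local refinement of the argmin within the bracketing grid cell: the
  # tangent construction is exact only at the true minimiser of N_g, so a
  # grid-snapping offset in b2_tilde propagates at first order into
  # b2_hat; polishing removes that discretisation error.
  lo <- sw$grid[max(i - 1L, 1L)]
  hi <- sw$grid[min(i + 1L, length(sw$grid))]
  if (hi > lo) {
    Nfun <- function(b2) {
      v <- newton_functional(series, b1, b2, step = config$derivative_step)
      if (!is.finite(v) || v <= 0) 1e300 else v
    }
    opt <- optimize(Nfun, interval = c(lo, hi), tol = 1e-4 * b2_tilde)
    if (opt$objective < 1e300) b2_tilde <- opt$minimum
  }
  N <- newton_functional(series, b1, b2_tilde, step = config$derivative_step)
  if (!is.finite(N) || N <= 0) N <- sw$N[i]   # fall back to the grid estimate
  list(b2_tilde = b2_tilde, b2_hat = b2_tilde + N, N = N,
       residual = residual_loss(series, b1, b2_tilde))
}

#' Estimate the feasibility-boundary curve in the (b1, b2) plane
#'
#' Traces the estimated boundary of the region where non-negatively
#' constrained impulses would fit noise-free data perfectly: for each b1 on
#' the configured grid, [estimate_b2_at()] supplies a point
#' \eqn{(b_1, \hat b_2(b_1))}; the discretised regression is then solved at
#' that point and sparsified (thresholding, refit, merging) to attach an
#' impulse estimate. Grid points where the inner problem fails are skipped.
#' Discontinuities of the curve are flagged where the surviving impulse
#' count changes between adjacent grid points (qualitative shifts of the
#' solution, e.g. an extra impulse appearing).
#'
#' The generating parameter pair lies on the true boundary, so on low-noise
#' data the curve passes close to it; under noise, points along the whole
#' curve give similar fits and the curve characterises the direction of
#' estimation uncertainty rather than a point estimate.
#'
#' @param series A [sampled_series()], preprocessed (basal-subtracted).
#' @param config A [curve_config()]; see [default_curve_config()].
#' @param warm_start Optional `gamma_curve` from a previous run on related
#'   data; the b2 search at each b1 is then narrowed to a window around
#'   the warm-start curve (local optimisation).
#' @return An object of class `gamma_curve`: a list with `points` (data
#'   frame with columns `b1`, `b2_tilde`, `b2_hat`, `residual`,
#'   `n_impulses`, `discontinuity`), `impulses` (list of per-point
#'   [impulse_train()]s) and the `config` used.
#' @export
estimate_gamma_curve <- function(series, config = default_curve_config(series),
                                 warm_start = NULL) {
  stopifnot(inherits(series, "sampled_series"),
            inherits(config, "curve_config"))
  if (!is.null(warm_start)) stopifnot(inherits(warm_start, "gamma_curve"))
  rows <- list()
  trains <- list()
  for (b1 in config$b1_grid) {
    cfg <- config
    if (!is.null(warm_start) && nrow(warm_start$points) > 0L) {
      ref <- warm_start$points
      b2_ref <- approx(ref$b1, ref$b2_hat, xout = b1, rule = 2)$y
      cfg$b2_min <- max(config$b2_min, b2_ref / 3)
      cfg$n_b2 <- max(50L, as.integer(config$n_b2 / 2L))
    }
    est <- estimate_b2_at(series, b1, cfg)
    if (is.null(est)) next
    b2_hat <- min(est$b2_hat, b1 * (1 - 1e-6))
    fit <- solve_weights(series, b1, b2_hat)
    sp <- sparsify_fit(fit, config$sparsify)
    rows[[length(rows) + 1L]] <-
      data.frame(b1 = b1, b2_tilde = est$b2_tilde, b2_hat = b2_hat,
                 residual = sp$fit$residual,
                 n_impulses = length(sp$impulses),
                 discontinuity = FALSE)
    trains[[length(trains) + 1L]] <- sp$impulses
  }
  if (length(rows) == 0L)
    stop("curve estimation failed at every b1 grid point", call. = FALSE)
  points <- do.call(rbind, rows)
  if (nrow(points) > 1L)
    points$discontinuity <- c(FALSE, diff(points$n_impulses) != 0)
  structure(list(points = points, impulses = trains, config = config),
            class = "gamma_curve")
}

#' @export
print.gamma_curve <- function(x, ...) {
  p <- x$points
  cat(sprintf("Estimated feasibility-boundary curve: %d points, b1 in [%.4g, %.4g]\n",
              nrow(p), min(p$b1), max(p$b1)))
  cat(sprintf("  b2_hat in [%.4g, %.4g]; impulse counts %s; %d discontinuit%s\n",
              min(p$b2_hat), max(p$b2_hat),
              paste(range(p$n_impulses), collapse = "-"),
              sum(p$discontinuity), if (sum(p$discontinuity) == 1L) "y" else "ies"))
  invisible(x)
}

#' @export
as.data.frame.gamma_curve <- function(x, ...) x$points
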