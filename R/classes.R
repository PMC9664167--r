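#' Plant parameters of the two-compartment elimination cascade
#'
#' Container for the linear part of the impulsive time-series model: a
#' cascade of two first-order eliminations in which an unobserved upstream
#' hormone (e.g. GnRH) with elimination rate `b1` stimulates an observed
#' downstream hormone (e.g. LH) with elimination rate `b2`. The stimulation
#' gain is not identifiable from output samples and is fixed to 1, which
#' amounts to expressing impulse weights in output-concentration units.
#'
#' @param b1 Elimination rate of the upstream hormone, 1/min. Must be > 0.
#' @param b2 Elimination rate of the observed hormone, 1/min. Must be > 0.
#' @param x2_init Observed concentration at the first sampling time
#'   (concentration units). Must be >= 0.
#' @return An object of class `plant_parameters`.
#' @examples
#' plant_parameters(b1 = 0.46, b2 = 0.011)
#' @export
plant_parameters <- function(b1, b2, x2_init = 0) {
  stopifnot(is.numeric(b1), length(b1) == 1L, is.finite(b1),
            is.numeric(b2), length(b2) == 1L, is.finite(b2),
            is.numeric(x2_init), length(x2_init) == 1L, is.finite(x2_init))
  if (b1 <= 0 || b2 <= 0)
    stop("elimination rates b1 and b2 must be positive", call. = FALSE)
  if (x2_init < 0)
    stop("initial concentration x2_init must be non-negative", call. = FALSE)
  structure(list(b1 = as.numeric(b1), b2 = as.numeric(b2),
                 g1 = 1, x2_init = as.numeric(x2_init)),
            class = "plant_parameters")
}

#' @export
print.plant_parameters <- function(x, ...) {
  cat("Plant parameters (two-compartment cascade, gain fixed to 1)\n")
  cat(sprintf("  b1 = %.5g /min (half-life %.3g min)\n", x$b1, half_life(x$b1)))
  cat(sprintf("  b2 = %.5g /min (half-life %.3g min)\n", x$b2, half_life(x$b2)))
  cat(sprintf("  x2(t1) = %.5g\n", x$x2_init))
  invisible(x)
}

#' Train of weighted instantaneous secretion impulses
#'
#' An ordered sequence of Dirac impulses at times `times` with positive
#' weights `weights`, modelling instantaneous secretion bursts of the
#' upstream hormone. Inside the discretised regression zero weights are
#' permitted (`allow_zero = TRUE`); a sparsified final estimate carries
#' strictly positive weights only.
#'
#' @param times Strictly increasing impulse times, min.
#' @param weights Impulse weights (concentration units, gain-normalised).
#' @param allow_zero Permit zero weights (used by the discretised solver).
#' @return An object of class `impulse_train`.
#' @examples
#' impulse_train(c(30, 240, 700), c(1.2, 0.8, 1.5))
#' @export
impulse_train <- function(times = numeric(0), weights = numeric(0),
                          allow_zero = FALSE) {
  times <- as.numeric(times); weights <- as.numeric(weights)
  stopifnot(length(times) == length(weights),
            all(is.finite(times)), all(is.finite(weights)))
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("impulse times must be strictly increasing", call. = FALSE)
  if (any(weights < 0) || (!allow_zero && any(weights == 0)))
    stop("impulse weights must be positive", call. = FALSE)
  structure(list(times = times, weights = weights), class = "impulse_train")
}

#' @export
print.impulse_train <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Impulse train: %d impulse%s\n", n, if (n == 1L) "" else "s"))
  if (n > 0L)
    print(data.frame(time_min = x$times, weight = x$weights),
          row.names = FALSE)
  invisible(x)
}

#' @export
length.impulse_train <- function(x) length(x$times)

#' Sampled concentration series
#'
#' Measurements of the observed hormone concentration at strictly increasing
#' sampling times, the data object consumed by every estimator in the
#' package.
#'
#' @param times Sampling times t_1 < ... < t_K, min. K >= 2.
#' @param values Measured concentrations (same length as `times`).
#' @return An object of class `sampled_series`.
#' @examples
#' sampled_series(seq(0, 60, by = 10), c(0.1, 2.1, 1.8, 1.5, 1.3, 1.1, 1.0))
#' @export
sampled_series <- function(times, values) {
  times <- as.numeric(times); values <- as.numeric(values)
  stopifnot(length(times) == length(values))
  if (length(times) < 2L)
    stop("a sampled series needs at least two samples", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("sampling times and values must be finite", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("sampling times must be strictly increasing", call. = FALSE)
  structure(list(times = times, values = values), class = "sampled_series")
}

#' @export
print.sampled_series <- function(x, ...) {
  K <- length(x$times)
  cat(sprintf("Sampled series: K = %d samples over [%.4g, %.4g] min\n",
              K, x$times[1L], x$times[K]))
  cat(sprintf("  concentration range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.sampled_series <- function(x) length(x$times)

#' @export
as.data.frame.sampled_series <- function(x, ...) {
  data.frame(time_min = x$times, concentration = x$values)
}

#' @export
as.data.frame.impulse_train <- function(x, ...) {
  data.frame(time_min = x$times, weight = x$weights)
}
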