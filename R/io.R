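#' Preprocessing specification
#'
#' Mirrors the standard cleanup applied to clinical pulsatile-hormone
#' records before estimation: manual exclusion of outlier samples
#' (detected by visual inspection; automatic outlier detectors are
#' typically not adapted to pulsatile signals and are deliberately not
#' shipped), optional restriction to a time window, and subtraction of the
#' record nadir to account for the unknown basal (non-pulsatile) level.
#'
#' @param basal_mode Subtract the nadir of the remaining values
#'   (default TRUE).
#' @param window Optional length-2 `[t_start, t_end]` window, min.
#' @param excluded_indices Zero-based sample indices to drop before
#'   windowing.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(basal_mode = TRUE, window = NULL,
                            excluded_indices = integer(0)) {
  if (!is.null(window))
    stopifnot(is.numeric(window), length(window) == 2L, window[1L] < window[2L])
  stopifnot(isTRUE(basal_mode) || isFALSE(basal_mode),
            all(excluded_indices >= 0))
  structure(list(basal_mode = basal_mode, window = window,
                 excluded_indices = as.integer(excluded_indices)),
            class = "preprocess_spec")
}

#' Preprocess a sampled series
#'
#' Applies, in order: exclusion of the listed sample indices, restriction
#' to the time window, and nadir subtraction (the minimum of the remaining
#' values is subtracted, so the resulting minimum is exactly 0). Sampling
#' times are otherwise unchanged.
#'
#' @param series A [sampled_series()].
#' @param spec A [preprocess_spec()].
#' @return A preprocessed [sampled_series()].
#' @examples
#' s <- sampled_series(c(0, 10, 20), c(3, 1, 2))
#' preprocess(s, preprocess_spec())$values  # 2 0 1
#' @export
preprocess <- function(series, spec = preprocess_spec()) {
  stopifnot(inherits(series, "sampled_series"),
            inherits(spec, "preprocess_spec"))
  t <- series$times
  v <- series$values
  if (length(spec$excluded_indices)) {
    drop <- spec$excluded_indices + 1L   # preprocess_spec indices are zero-based
    if (any(drop > length(t)))
      stop("excluded index outside the record", call. = FALSE)
    t <- t[-drop]; v <- v[-drop]
  }
  if (!is.null(spec$window)) {
    keep <- t >= spec$window[1L] & t <= spec$window[2L]
    if (sum(keep) < 2L)
      stop("window leaves fewer than two samples", call. = FALSE)
    t <- t[keep]; v <- v[keep]
  }
  if (spec$basal_mode) v <- v - min(v)
  sampled_series(t, v)
}

#' Summary statistics of an impulse train
#'
#' Per-record averages used to characterise pulsatility: the mean
#' consecutive impulse-time separation and the mean impulse weight
#' (gain-normalised, i.e. in the concentration unit of the input series).
#'
#' @param impulses An [impulse_train()] with >= 1 impulse.
#' @return An object of class `impulse_summary`: list with `n_impulses`,
#'   `mean_separation` (min; `NA` for fewer than two impulses) and
#'   `mean_weight`.
#' @examples
#' summarize_impulses(impulse_train(c(0, 10, 30), c(1, 2, 3)))
#' @export
summarize_impulses <- function(impulses) {
  stopifnot(inherits(impulses, "impulse_train"))
  n <- length(impulses)
  if (n < 1L) stop("at least one impulse required", call. = FALSE)
  structure(list(n_impulses = n,
                 mean_separation = if (n >= 2L) mean(diff(impulses$times))
                                   else NA_real_,
                 mean_weight = mean(impulses$weights)),
            class = "impulse_summary")
}

#' @export
print.impulse_summary <- function(x, ...) {
  cat(sprintf("Impulse summary: n = %d, mean separation = %s min, mean weight = %.4g\n",
              x$n_impulses,
              if (is.na(x$mean_separation)) "undefined (single impulse)"
              else sprintf("%.4g", x$mean_separation),
              x$mean_weight))
  invisible(x)
}

#' Check elimination rates against the theoretical ranges
#'
#' Compares a (b1, b2) pair with the biochemically established closed
#' boxes for the GnRH and LH elimination rates,
#' 0.23 <= b1 <= 0.69 /min and 0.0087 <= b2 <= 0.014 /min (boundary values
#' count as inside). Signed margins are positive outside the box (distance
#' beyond the nearer bound) and negative inside.
#'
#' @param b1,b2 Positive rates, 1/min.
#' @param b1_range,b2_range Closed boxes (defaults above).
#' @return An object of class `rate_bounds`: list with per-rate `inside`
#'   verdicts and signed `margin`s.
#' @examples
#' check_rate_bounds(0.5, 0.016)  # b2 outside by +0.002
#' @export
check_rate_bounds <- function(b1, b2, b1_range = c(0.23, 0.69),
                              b2_range = c(0.0087, 0.014)) {
  stopifnot(b1 > 0, b2 > 0)
  margin <- function(x, r) {
    if (x < r[1L]) r[1L] - x
    else if (x > r[2L]) x - r[2L]
    else -min(x - r[1L], r[2L] - x)
  }
  structure(list(b1 = list(inside = b1 >= b1_range[1L] & b1 <= b1_range[2L],
                           margin = margin(b1, b1_range), range = b1_range),
                 b2 = list(inside = b2 >= b2_range[1L] & b2 <= b2_range[2L],
                           margin = margin(b2, b2_range), range = b2_range)),
            class = "rate_bounds")
}

#' @export
print.rate_bounds <- function(x, ...) {
  for (nm in c("b1", "b2")) {
    r <- x[[nm]]
    cat(sprintf("  %s: %s theoretical range [%.4g, %.4g] (signed margin %+.4g)\n",
                nm, if (r$inside) "inside" else "OUTSIDE",
                r$range[1L], r$range[2L], r$margin))
  }
  invisible(x)
}

#' Read and write the package's CSV formats
#'
#' Series CSV has header `time_min,concentration`; impulse CSV has
#' `time_min,weight`; curve CSV has the columns of the `gamma_curve`
#' points data frame. Round-trips are value-exact for finite inputs
#' (values are written at full double precision).
#'
#' @param path File path.
#' @return `read_series()` a [sampled_series()]; `read_impulses()` an
#'   [impulse_train()]; `read_curve()` a data frame of curve points.
#'   Writers return `path` invisibly.
#' @name series_io
NULL

fmt_full <- function(x) formatC(x, digits = 17, format = "g")

#' @rdname series_io
#' @param series A [sampled_series()].
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "sampled_series"))
  df <- data.frame(time_min = fmt_full(series$times),
                   concentration = fmt_full(series$values))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname series_io
#' @export
read_series <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("time_min", "concentration") %in% names(df)))
  sampled_series(df$time_min, df$concentration)
}

#' @rdname series_io
#' @param impulses An [impulse_train()].
#' @export
write_impulses <- function(impulses, path) {
  stopifnot(inherits(impulses, "impulse_train"))
  df <- data.frame(time_min = fmt_full(impulses$times),
                   weight = fmt_full(impulses$weights))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname series_io
#' @export
read_impulses <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("time_min", "weight") %in% names(df)))
  impulse_train(df$time_min, df$weight)
}

#' @rdname series_io
#' @param curve A `gamma_curve` from [estimate_gamma_curve()].
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "gamma_curve"))
  p <- curve$points
  df <- data.frame(b1 = fmt_full(p$b1), b2_tilde = fmt_full(p$b2_tilde),
                   b2_hat = fmt_full(p$b2_hat),
                   residual = fmt_full(p$residual),
                   n_impulses = p$n_impulses,
                   discontinuity = p$discontinuity)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname series_io
#' @export
read_curve <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("b1", "b2_tilde", "b2_hat", "residual", "n_impulses",
                  "discontinuity") %in% names(df)))
  df
}

#' Serialise posterior chains
#'
#' Writes one CSV per chain (one row per retained iteration, parameter
#' columns plus log-posterior and acceptance indicator) and a JSON run
#' manifest (seeds, configuration, acceptance rates).
#'
#' @param chains List of `posterior_chain` objects from
#'   [run_adaptive_metropolis()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the manifest path.
#' @export
write_chains <- function(chains, dir, prefix = "chain") {
  stopifnot(is.list(chains),
            all(vapply(chains, inherits, logical(1L), "posterior_chain")))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    df <- as.data.frame(ch$samples)
    df$log_posterior <- ch$log_posterior
    df$accepted <- as.integer(ch$accept)
    write.csv(df, file.path(dir, sprintf("%s_%d.csv", prefix, i)),
              row.names = FALSE)
  }
  cfg <- chains[[1L]]$config
  manifest <- list(
    n_chains = length(chains),
    seeds = vapply(chains, `[[`, integer(1L), "seed"),
    acceptance_rate = vapply(chains, function(ch) mean(ch$accept), numeric(1L)),
    config = unclass(cfg))
  mpath <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}
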