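# Observables extracted from simulation traces: stationarity onset, the
# asymptotic current (bioluminescence analogue), oscillation frequency, and
# power-law exponents across q_max.  Onset and BA share one stationarity
# rule so the two never drift apart.

onset_from_series <- function(x) {
  n <- length(x)
  if (n < 4L) stop("series too short to detect a stationary segment", call. = FALSE)
  ref <- mean(x[(n %/% 2 + 1L):n])      # trailing-half mean
  hit <- which(x >= 0.9 * ref)
  if (!length(hit) || hit[1L] > 0.9 * n)
    stop("no stationary segment detected; increase n_steps", call. = FALSE)
  hit[1L]
}

#' Stationarity onset of a trace
#'
#' The onset is the first iteration at which the total c-charge reaches 90
#' percent of its trailing-half mean.  The same rule delimits the stationary
#' segment used by [asymptotic_ba()] and [oscillation_frequency()].
#'
#' @param trace a `qs_trace` (or anything with a `total_charge` column).
#' @return integer iteration index.
#' @export
onset_time <- function(trace) {
  onset_from_series(as.numeric(trace$total_charge))
}

#' Asymptotic bioluminescence analogue of a run
#'
#' The bioluminescence analogue BA is the mean of the fictitious total
#' current over the stationary segment of a run (the non-stationary initial
#' stage is cut off at the [onset_time()]).  The standard error accounts for
#' the serial correlation of the oscillating current through batch means.
#'
#' @param trace a `qs_trace` whose readout was computed (`gamma` non-NULL).
#' @param column which readout gamma column to use (default 1).
#' @param n_batch number of batches for the batch-means standard error.
#' @return list with `ba`, `se`, `onset`, `n` (stationary steps used).
#' @export
asymptotic_ba <- function(trace, column = 1L, n_batch = 8L) {
  cur <- attr(trace, "current")
  if (is.null(cur)) cur <- matrix(trace$current, ncol = 1L)
  if (ncol(cur) < column)
    stop("trace carries no current readout; rerun with a non-NULL gamma", call. = FALSE)
  y <- cur[, column]
  if (all(is.na(y)))
    stop("trace carries no current readout; rerun with a non-NULL gamma", call. = FALSE)
  onset <- onset_time(trace)
  seg <- y[onset:length(y)]
  n <- length(seg)
  ba <- mean(seg)
  se <- 0
  if (n >= 2L && stats::sd(seg) > 0) {
    nb <- max(2L, min(n_batch, n %/% 2L))
    bm <- tapply(seg, cut(seq_len(n), nb, labels = FALSE), mean)
    se <- stats::sd(bm) / sqrt(nb)
  }
  list(ba = ba, se = se, onset = onset, n = n)
}

#' Dominant oscillation frequency of the stationary total charge
#'
#' Removes the mean of the stationary segment, applies a Hann taper, and
#' locates the largest nonzero-frequency peak of the discrete spectrum.
#' Frequencies are in cycles per iteration (at most 0.5, the per-step
#' sampling limit); the resolution is one bin, `1/n` for a segment of `n`
#' steps, reported as `bin_width`.
#'
#' @param trace a `qs_trace`, or a numeric series via `series`.
#' @param series optional numeric series used instead of the trace's total
#'   charge (the stationarity cut is then skipped).
#' @return an `oscillation_summary`: list with `dominant_frequency`,
#'   `amplitude`, `stationary_mean`, `onset_step`, `bin_width`.
#' @export
oscillation_frequency <- function(trace = NULL, series = NULL) {
  if (is.null(series)) {
    x <- as.numeric(trace$total_charge)
    onset <- onset_from_series(x)
    seg <- x[onset:length(x)]
  } else {
    seg <- as.numeric(series)
    onset <- 1L
  }
  n <- length(seg)
  if (n < 8L) stop("stationary segment too short for spectral analysis", call. = FALSE)
  mu <- mean(seg)
  y <- seg - mu
  if (stats::sd(seg) == 0) stop("no oscillation detected: series is constant", call. = FALSE)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))   # Hann taper
  sp <- abs(stats::fft(y * w))[1:(n %/% 2 + 1L)]
  sp[1L] <- 0                                 # exclude the zero-frequency bin
  k <- which.max(sp)
  if (sp[k] == 0) stop("no oscillation detected", call. = FALSE)
  out <- list(dominant_frequency = (k - 1) / n,
              amplitude = 2 * sp[k] / sum(w),
              stationary_mean = mu,
              onset_step = onset,
              bin_width = 1 / n)
  class(out) <- "oscillation_summary"
  out
}

#' @export
print.oscillation_summary <- function(x, ...) {
  cat(sprintf("dominant frequency: %.4f cycles/iteration (bin width %.4f)\n",
              x$dominant_frequency, x$bin_width))
  cat(sprintf("amplitude: %.3g   stationary mean: %.3g   onset: step %d\n",
              x$amplitude, x$stationary_mean, x$onset_step))
  invisible(x)
}

#' Power-law exponent by log-log least squares
#'
#' Fits `log(y) ~ log(x)` by ordinary least squares and returns the slope
#' (the power-law exponent), its standard error and the R-squared.
#'
#' @param x,y positive numeric vectors (at least 3 points).
#' @return list with `exponent`, `se`, `r_squared`, `prefactor`.
#' @export
powerlaw_exponent <- function(x, y) {
  if (length(x) < 3L || length(x) != length(y))
    stop("need at least 3 (x, y) pairs", call. = FALSE)
  if (any(x <= 0) || any(y <= 0))
    stop("power-law fit requires strictly positive values", call. = FALSE)
  fit <- stats::lm(log(y) ~ log(x))
  sm <- suppressWarnings(summary(fit))   # exact power laws fit perfectly
  list(exponent = unname(stats::coef(fit)[2L]),
       se = sm$coefficients[2L, 2L],
       r_squared = sm$r.squared,
       prefactor = exp(unname(stats::coef(fit)[1L])))
}
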