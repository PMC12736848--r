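#' Uniformly sampled time series
#'
#' Light-weight container for a uniformly sampled signal: a numeric vector of
#' values, a sampling rate in Hz and a start time in seconds. All raw and
#' filtered channels in the pipeline (triaxial wire forces at 1000 Hz, digit
#' wrench components, vertical object position at 120 Hz) are carried in this
#' form.
#'
#' @param values numeric vector, length >= 2, all finite.
#' @param rate sampling rate in samples per second; must be > 0.
#' @param t0 time of the first sample, in seconds.
#' @return An object of class `uniform_series` with fields `values`, `rate`,
#'   `t0`.
#' @export
uniform_series <- function(values, rate, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop_beadmaze("a uniform series needs at least 2 samples", "invalid_series")
  if (!all(is.finite(values)))
    stop_beadmaze("series values must all be finite", "invalid_series")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop_beadmaze("`rate` must be a single positive number (Hz)", "invalid_series")
  structure(list(values = values, rate = as.numeric(rate), t0 = as.numeric(t0)),
            class = "uniform_series")
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %d samples @ %g Hz, t0 = %g s, range [%.4g, %.4g]\n",
              length(x$values), x$rate, x$t0, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.uniform_series <- function(x) length(x$values)

#' Sample times of a uniform series
#'
#' @param series a [uniform_series()].
#' @return Numeric vector of sample times in seconds.
#' @export
series_times <- function(series) {
  series$t0 + (seq_along(series$values) - 1) / series$rate
}

# classed error helper so callers can condition on failure modes
stop_beadmaze <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("beadmaze_", class), "beadmaze_error")))
}

as_index_window <- function(window, n) {
  window <- as.integer(window)
  if (length(window) != 2L || anyNA(window))
    stop_beadmaze("a window must be two integer indices c(start, end)", "invalid_window")
  if (window[1] > window[2])
    stop_beadmaze("window start must not exceed window end", "invalid_window")
  if (window[1] < 1L || window[2] > n)
    stop_beadmaze(sprintf("window [%d, %d] lies outside the series (length %d)",
                          window[1], window[2], n), "invalid_window")
  window
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass filter forward and backward
#' (forward-backward cascade, so the net phase delay is zero and the
#' effective magnitude response is the squared Butterworth response). Edge
#' transients are suppressed by odd (point-mirrored) reflection padding of
#' three times the filter order at each end, removed after filtering.
#'
#' @param series a [uniform_series()].
#' @param cutoff_hz -3 dB cutoff of the single-pass design, strictly between 0
#'   and the Nyquist frequency `rate/2`.
#' @param order single-pass filter order (>= 1); the default 5 gives an
#'   effective 10th-order magnitude response after the double pass.
#' @return A `uniform_series` of the same length, rate and start time.
#' @export
lowpass_zero_phase <- function(series, cutoff_hz, order = 5L) {
  stopifnot(inherits(series, "uniform_series"))
  nyq <- series$rate / 2
  if (!is.numeric(cutoff_hz) || length(cutoff_hz) != 1L || !is.finite(cutoff_hz) ||
      cutoff_hz <= 0 || cutoff_hz >= nyq)
    stop_beadmaze(sprintf("`cutoff_hz` must lie strictly between 0 and Nyquist (%g Hz)", nyq),
                  "invalid_cutoff")
  order <- as.integer(order)
  if (is.na(order) || order < 1L)
    stop_beadmaze("`order` must be an integer >= 1", "invalid_order")
  x <- series$values
  pad <- 3L * order
  if (length(x) <= pad + 1L)
    stop_beadmaze(sprintf("series too short to filter: need > %d samples, got %d",
                          pad + 1L, length(x)), "series_too_short")
  ba <- signal::butter(order, cutoff_hz / nyq, type = "low")
  left  <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[length(x)] - x[seq(length(x) - 1L, length(x) - pad)]
  xp <- c(left, x, right)
  y <- iir_filter(ba$b, ba$a, xp)
  y <- rev(iir_filter(ba$b, ba$a, rev(y)))
  uniform_series(y[(pad + 1L):(pad + length(x))], series$rate, series$t0)
}

# single-pass IIR filter (direct form I) with steady-state initialization:
# the filter starts as if the input had been at its first value forever, so a
# constant passes through exactly and startup transients do not leak past the
# reflection padding
iir_filter <- function(b, a, x) {
  b <- b / a[1L]; a <- a / a[1L]
  g0 <- sum(b) / sum(a)                       # DC gain
  nb <- length(b)
  xp <- c(rep(x[1L], nb - 1L), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:length(xp)]
  y <- stats::filter(v, -a[-1L], method = "recursive",
                     init = rep(g0 * x[1L], length(a) - 1L))
  as.numeric(y)
}

#' White-noise gain of the zero-phase low-pass filter
#'
#' Standard deviation ratio (output/input) for white Gaussian noise passed
#' through [lowpass_zero_phase()], computed from the impulse response of the
#' forward-backward cascade. Used by the synthetic generators to plant event
#' times against the detection band the pipeline will actually estimate from
#' filtered baseline noise.
#'
#' @inheritParams lowpass_zero_phase
#' @param rate sampling rate in Hz.
#' @return Scalar gain in (0, 1].
#' @export
lowpass_noise_gain <- function(rate, cutoff_hz, order = 5L) {
  n <- max(4096L, as.integer(round(rate)))  # long enough for the tail to decay
  imp <- c(rep(0, n %/% 2), 1, rep(0, n - n %/% 2 - 1))
  h <- lowpass_zero_phase(uniform_series(imp, rate), cutoff_hz, order)
  sqrt(sum(h$values^2))
}

#' Baseline mean and standard deviation
#'
#' Mean and sample standard deviation (n - 1 denominator) over an index
#' window, used to form the `mean +/- 2 SD` detection bands for trial-start
#' and lift-onset detection.
#'
#' @param series a [uniform_series()].
#' @param window integer `c(start, end)`, 1-based inclusive, inside the series.
#' @return List with `mean`, `sd` and the validated `window`.
#' @export
baseline_stats <- function(series, window) {
  stopifnot(inherits(series, "uniform_series"))
  window <- as_index_window(window, length(series$values))
  v <- series$values[window[1]:window[2]]
  s <- if (length(v) > 1L) stats::sd(v) else 0
  list(mean = mean(v), sd = s, window = window)
}

#' First sustained threshold crossing
#'
#' Finds the first index `i` such that every sample in the run
#' `[i, i + ceiling(min_duration_s * rate) - 1]` lies strictly above (or
#' strictly below) the threshold. Samples exactly equal to the threshold never
#' count. Absence of such a run is a valid result, returned as `NA`.
#'
#' @param series a [uniform_series()].
#' @param threshold crossing level, in the series' units.
#' @param direction `"above"` or `"below"`.
#' @param min_duration_s minimum sustained duration in seconds; must be at
#'   least one sample period.
#' @return Integer index (1-based) of the start of the first qualifying run,
#'   or `NA_integer_` if none exists.
#' @export
sustained_crossing <- function(series, threshold, direction = c("above", "below"),
                               min_duration_s) {
  stopifnot(inherits(series, "uniform_series"))
  direction <- match.arg(direction)
  if (min_duration_s < 1 / series$rate)
    stop_beadmaze("`min_duration_s` must be at least one sample period", "invalid_duration")
  m <- as.integer(ceiling(min_duration_s * series$rate))
  sat <- if (direction == "above") series$values > threshold else series$values < threshold
  r <- rle(sat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= m
  if (!any(ok)) return(NA_integer_)
  as.integer(starts[which(ok)[1L]])
}

#' Linear-interpolation resampling
#'
#' Resamples a series onto a uniform grid at (approximately) the target rate
#' spanning exactly the same time interval: the first and last time points are
#' preserved, and the realized rate is the closest rate to `target_rate` for
#' which the interval divides evenly. Used to bring 120 Hz position data onto
#' the 1000 Hz force time base.
#'
#' @param series a [uniform_series()].
#' @param target_rate requested sampling rate in Hz (> 0).
#' @return A `uniform_series` on the new grid.
#' @export
resample_to <- function(series, target_rate) {
  stopifnot(inherits(series, "uniform_series"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L || target_rate <= 0)
    stop_beadmaze("`target_rate` must be a single positive rate in Hz", "invalid_rate")
  n <- length(series$values)
  if (n < 2L)
    stop_beadmaze("cannot resample a single-sample series", "series_too_short")
  duration <- (n - 1) / series$rate
  nn <- as.integer(round(duration * target_rate)) + 1L
  if (nn < 2L) nn <- 2L
  t_old <- series_times(series)
  t_new <- seq(series$t0, series$t0 + duration, length.out = nn)
  vals <- stats::approx(t_old, series$values, xout = t_new, method = "linear")$y
  uniform_series(vals, (nn - 1) / duration, series$t0)
}
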