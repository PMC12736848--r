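#' Triaxial force trace
#'
#' One BMHFT recording: three force channels (N) sharing a sampling rate and
#' length, as produced by a triaxial transducer under the wire while a bead is
#' drawn along it.
#'
#' @param fx,fy,fz numeric vectors or [uniform_series()] objects of equal
#'   length; forces in newtons. `fy` is the horizontal channel carrying the
#'   stereotyped end-of-trial drop.
#' @param rate sampling rate in Hz (ignored when channels are already series).
#' @param subject_id,trial_id identifiers carried through to score tables.
#' @param wire_shape label for the wire; the scorer itself is wire-agnostic.
#' @return Object of class `force_trace`.
#' @export
force_trace <- function(fx, fy, fz, rate = 1000, subject_id = NA_character_,
                        trial_id = NA_integer_, wire_shape = "double_curve") {
  ch <- lapply(list(fx = fx, fy = fy, fz = fz), function(v) {
    if (inherits(v, "uniform_series")) v else uniform_series(v, rate)
  })
  ns <- vapply(ch, function(s) length(s$values), integer(1))
  rs <- vapply(ch, function(s) s$rate, numeric(1))
  if (length(unique(ns)) != 1L || length(unique(rs)) != 1L)
    stop_beadmaze("fx, fy, fz must share one length and one sampling rate", "invalid_trace")
  structure(list(fx = ch$fx, fy = ch$fy, fz = ch$fz, rate = rs[[1]],
                 subject_id = subject_id, trial_id = trial_id,
                 wire_shape = wire_shape),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace> subject %s trial %s (%s): %d samples @ %g Hz\n",
              x$subject_id, x$trial_id, x$wire_shape, length(x$fx$values), x$rate))
  invisible(x)
}

trace_channels <- c("fx", "fy", "fz")

map_channels <- function(trace, f) {
  out <- trace
  for (ch in trace_channels) out[[ch]] <- f(trace[[ch]])
  out
}

#' Remove per-channel DC offset
#'
#' Shifts each channel so its mean over the baseline window is zero, removing
#' transducer offset before event detection.
#'
#' @param trace a [force_trace()].
#' @param baseline_window integer `c(start, end)` indices; default = first
#'   200 ms.
#' @return The shifted `force_trace`.
#' @export
remove_dc_offset <- function(trace, baseline_window = NULL) {
  stopifnot(inherits(trace, "force_trace"))
  if (is.null(baseline_window))
    baseline_window <- c(1L, max(2L, round(0.2 * trace$rate)))
  map_channels(trace, function(s) {
    bs <- baseline_stats(s, baseline_window)
    uniform_series(s$values - bs$mean, s$rate, s$t0)
  })
}

#' Low-pass filter all channels of a trace
#'
#' @param trace a [force_trace()].
#' @param cutoff_hz,order passed to [lowpass_zero_phase()]; defaults 30 Hz,
#'   5th order.
#' @return The filtered `force_trace`.
#' @export
preprocess_trace <- function(trace, cutoff_hz = 30, order = 5L) {
  stopifnot(inherits(trace, "force_trace"))
  map_channels(trace, function(s) lowpass_zero_phase(s, cutoff_hz, order))
}

#' Per-channel baseline statistics of a trace
#'
#' @inheritParams remove_dc_offset
#' @return Named list of [baseline_stats()] results for fx, fy, fz.
#' @export
trace_baseline <- function(trace, baseline_window = NULL) {
  stopifnot(inherits(trace, "force_trace"))
  if (is.null(baseline_window))
    baseline_window <- c(1L, max(2L, round(0.2 * trace$rate)))
  lapply(list(fx = trace$fx, fy = trace$fy, fz = trace$fz),
         baseline_stats, window = baseline_window)
}

#' Detect trial start (bead contact)
#'
#' The trial starts at the first moment any force channel leaves its baseline
#' band (mean +/- `k_sd` SD, two-sided by default since contact may push or
#' pull) and stays out for at least `min_duration_s`. The earliest qualifying
#' index over the three channels is returned, with the detecting channel as
#' attribute `"channel"`.
#'
#' @param trace a preprocessed [force_trace()].
#' @param baseline list as returned by [trace_baseline()].
#' @param k_sd band half-width in baseline SDs (default 2).
#' @param min_duration_s sustained duration (default 0.010 s).
#' @param two_sided if `FALSE`, only upward exceedance counts.
#' @return Integer start index; errors with class `beadmaze_no_trial` if no
#'   channel ever leaves its band.
#' @export
find_trial_start <- function(trace, baseline = trace_baseline(trace), k_sd = 2,
                             min_duration_s = 0.010, two_sided = TRUE) {
  stopifnot(inherits(trace, "force_trace"))
  idx <- vapply(trace_channels, function(ch) {
    s <- trace[[ch]]
    bs <- baseline[[ch]]
    dev <- if (two_sided) abs(s$values - bs$mean) else s$values - bs$mean
    sustained_crossing(uniform_series(dev, s$rate, s$t0), k_sd * bs$sd,
                       "above", min_duration_s)
  }, integer(1))
  if (all(is.na(idx)))
    stop_beadmaze("no trial detected: no channel left its baseline band", "no_trial")
  i <- which.min(idx)
  structure(idx[[i]], channel = trace_channels[[i]])
}

#' Detect trial end (bead reaches the stationary bead)
#'
#' The trial ends at the first sample after `start_index` where the filtered,
#' DC-removed y-force reaches the stereotyped contact drop: `fy <=
#' end_threshold` (default -0.2 N).
#'
#' @param trace a preprocessed [force_trace()].
#' @param start_index detected trial start.
#' @param end_threshold drop level in newtons (default -0.2).
#' @return Integer end index; errors with class `beadmaze_no_end` if the
#'   y-force never reaches the threshold after the start.
#' @export
find_trial_end <- function(trace, start_index, end_threshold = -0.2) {
  stopifnot(inherits(trace, "force_trace"))
  n <- length(trace$fy$values)
  if (start_index < 1L || start_index >= n)
    stop_beadmaze("`start_index` out of range", "invalid_index")
  tail_idx <- which(trace$fy$values[(start_index + 1L):n] <= end_threshold)
  if (length(tail_idx) == 0L)
    stop_beadmaze(sprintf("no trial end detected: fy never reached %g N", end_threshold),
                  "no_end")
  as.integer(start_index + tail_idx[1L])
}

#' Trial segment
#'
#' @param start_index,end_index 1-based sample indices, start < end.
#' @param rate sampling rate in Hz.
#' @return List with `start_index`, `end_index`, `duration_s`.
#' @export
trial_segment <- function(start_index, end_index, rate) {
  start_index <- as.integer(start_index); end_index <- as.integer(end_index)
  if (is.na(start_index) || is.na(end_index) || start_index < 1L ||
      start_index >= end_index)
    stop_beadmaze("need 1 <= start_index < end_index", "invalid_segment")
  list(start_index = start_index, end_index = end_index,
       duration_s = (end_index - start_index) / rate)
}

#' L1-norm total force over a trial
#'
#' Sums `|fx| + |fy| + |fz|` over the segment, endpoints inclusive (contact is
#' the trial start). The headline `total_force` is the raw per-sample sum,
#' which matches summation at the instrument's fixed 1000 Hz rate; the
#' rate-normalized time integral (N s) is always co-reported so that traces
#' recorded at different rates remain comparable.
#'
#' @param trace a [force_trace()] (normally DC-removed and filtered).
#' @param segment a [trial_segment()].
#' @return List of class `bmhft_score`: `total_force` (N per sample, summed),
#'   `total_force_integral` (N s), `duration_s`, `rate`, `qc_flags`.
#' @export
total_force_l1 <- function(trace, segment) {
  stopifnot(inherits(trace, "force_trace"))
  n <- length(trace$fx$values)
  if (segment$start_index < 1L || segment$end_index > n ||
      segment$start_index >= segment$end_index)
    stop_beadmaze("segment empty or outside the trace", "invalid_segment")
  w <- segment$start_index:segment$end_index
  tf <- sum(abs(trace$fx$values[w]) + abs(trace$fy$values[w]) + abs(trace$fz$values[w]))
  structure(list(total_force = tf,
                 total_force_integral = tf / trace$rate,
                 duration_s = segment$duration_s,
                 rate = trace$rate,
                 subject_id = trace$subject_id,
                 trial_id = trace$trial_id,
                 qc_flags = character()),
            class = "bmhft_score")
}

#' Segment and score one BMHFT trial
#'
#' Full single-trial chain: DC removal over the baseline window, zero-phase
#' low-pass filtering, baseline band estimation, trial start/end detection,
#' and L1 total force over the detected segment. Event detection failures
#' and suspicious segmentations do not stop the run; they are recorded as QC
#' flags (`no_trial_detected`, `no_end_detected`, `short_segment` for
#' durations under 0.2 s, `multiple_end_candidates` when several distinct
#' threshold entries occur within 50 ms of the chosen end).
#'
#' By default (`config$baseline_on = "raw"`) the baseline SD is estimated on
#' the raw DC-removed signal while the sustained-crossing rule runs on the
#' filtered signal. Low-pass filtering attenuates white baseline noise
#' several-fold, so the raw-SD band is deliberately conservative on the
#' filtered trace; estimating the band on the filtered baseline itself
#' (`baseline_on = "filtered"`) makes 2 SD excursions lasting 10 ms near
#' certain on band-limited noise, which is why the original protocol needed
#' each detection visually confirmed. The conservative default replaces that
#' human check.
#'
#' @param trace a raw [force_trace()].
#' @param config list of thresholds, see [default_config()].
#' @return List with `segment` (or `NULL`), `score` (or `NULL`), `qc_flags`,
#'   and the filtered trace in `filtered`.
#' @export
score_bmhft_trial <- function(trace, config = default_config()) {
  stopifnot(inherits(trace, "force_trace"))
  bw <- c(1L, max(2L, round(config$baseline_window_s * trace$rate)))
  trd <- remove_dc_offset(trace, bw)
  trf <- preprocess_trace(trd, config$cutoff_hz, config$filter_order)
  bs <- trace_baseline(if (identical(config$baseline_on, "filtered")) trf else trd,
                       bw)
  qc <- character()
  start <- tryCatch(
    find_trial_start(trf, bs, config$k_sd, config$start_min_duration_s,
                     config$two_sided_start),
    beadmaze_no_trial = function(e) { NA_integer_ })
  if (is.na(start))
    return(list(segment = NULL, score = NULL,
                qc_flags = "no_trial_detected", filtered = trf))
  end <- tryCatch(find_trial_end(trf, start, config$end_threshold_n),
                  beadmaze_no_end = function(e) NA_integer_)
  if (is.na(end))
    return(list(segment = NULL, score = NULL,
                qc_flags = "no_end_detected", filtered = trf))
  # entries into the end band within 50 ms after the chosen end
  fy <- trf$fy$values
  below <- fy[(start + 1L):length(fy)] <= config$end_threshold_n
  entries <- which(below & !c(FALSE, below[-length(below)])) + start
  near <- entries[entries > end & entries <= end + round(0.05 * trf$rate)]
  if (length(near) > 0L) qc <- c(qc, "multiple_end_candidates")
  seg <- trial_segment(start, end, trf$rate)
  if (seg$duration_s < 0.2) qc <- c(qc, "short_segment")
  score <- total_force_l1(trf, seg)
  score$qc_flags <- qc
  list(segment = seg, score = score, qc_flags = qc, filtered = trf)
}

#' Per-subject BMHFT summary score
#'
#' Arithmetic mean of per-trial total forces; the protocol uses 5 trials per
#' subject, so any other count is flagged (and warned about) but still
#' averaged. Refuses to average trials recorded at different sampling rates,
#' since the raw per-sample sum is rate-dependent.
#'
#' @param scores list of `bmhft_score` objects (valid trials only).
#' @param expected_trials protocol trial count (default 5).
#' @return List: `mean_total_force`, `mean_total_force_integral`,
#'   `mean_duration_s`, `n_trials`, `qc_flags`.
#' @export
score_subject <- function(scores, expected_trials = 5L) {
  scores <- Filter(Negate(is.null), scores)
  if (length(scores) == 0L)
    stop_beadmaze("no valid trials to average", "no_trials")
  rates <- vapply(scores, function(s) s$rate, numeric(1))
  if (length(unique(rates)) != 1L)
    stop_beadmaze("refusing to average total force across differing sampling rates",
                  "rate_mismatch")
  qc <- character()
  if (length(scores) != expected_trials) {
    qc <- "unexpected_trial_count"
    warning(sprintf("averaging %d trials where %d were expected",
                    length(scores), expected_trials), call. = FALSE)
  }
  list(mean_total_force = mean(vapply(scores, `[[`, numeric(1), "total_force")),
       mean_total_force_integral =
         mean(vapply(scores, `[[`, numeric(1), "total_force_integral")),
       mean_duration_s = mean(vapply(scores, `[[`, numeric(1), "duration_s")),
       n_trials = length(scores),
       qc_flags = qc)
}
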