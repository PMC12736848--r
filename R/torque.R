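#' Digit wrench streams
#'
#' Per-digit contact mechanics from one grip-surface force/torque sensor:
#' normal (grip) force, vertical tangential (load) force, and vertical
#' centre-of-pressure location in the grip-surface frame.
#'
#' @param fn normal force (N), [uniform_series()] or numeric.
#' @param ftan vertical tangential force (N).
#' @param cop_y vertical centre-of-pressure coordinate (mm).
#' @param rate sampling rate in Hz when plain vectors are given.
#' @return Object of class `digit_wrench`.
#' @export
digit_wrench <- function(fn, ftan, cop_y, rate = 1000) {
  ch <- lapply(list(fn = fn, ftan = ftan, cop_y = cop_y), function(v) {
    if (inherits(v, "uniform_series")) v else uniform_series(v, rate)
  })
  ns <- vapply(ch, function(s) length(s$values), integer(1))
  rs <- vapply(ch, function(s) s$rate, numeric(1))
  if (length(unique(ns)) != 1L || length(unique(rs)) != 1L)
    stop_beadmaze("fn, ftan, cop_y must share one length and one rate", "invalid_wrench")
  structure(c(ch, list(rate = rs[[1]])), class = "digit_wrench")
}

#' One grip-and-lift trial
#'
#' @param thumb,fingers [digit_wrench()] streams for the two grip surfaces,
#'   common rate and length.
#' @param position_z vertical object position (mm), [uniform_series()],
#'   nominally 120 Hz.
#' @param condition hidden-mass location: `"left"`, `"center"` or `"right"`.
#' @param grip_width_mm distance between the two grip surfaces; default 50 mm
#'   (the device's 5 cm total width).
#' @return Object of class `lift_trial`.
#' @export
lift_trial <- function(thumb, fingers, position_z, condition,
                       grip_width_mm = 50) {
  stopifnot(inherits(thumb, "digit_wrench"), inherits(fingers, "digit_wrench"),
            inherits(position_z, "uniform_series"))
  condition <- match.arg(condition, c("left", "center", "right"))
  if (!is.numeric(grip_width_mm) || grip_width_mm <= 0)
    stop_beadmaze("`grip_width_mm` must be > 0", "invalid_trial")
  if (length(thumb$fn$values) != length(fingers$fn$values) ||
      thumb$rate != fingers$rate)
    stop_beadmaze("thumb and fingers streams must share length and rate", "invalid_trial")
  structure(list(thumb = thumb, fingers = fingers, position_z = position_z,
                 condition = condition, grip_width_mm = grip_width_mm),
            class = "lift_trial")
}

#' Detect lift onset from vertical position
#'
#' Object lift onset is the first time the vertical position crosses and
#' remains above its baseline mean + `k_sd` SD for `min_duration_s` (default
#' 200 ms). The position stream is first resampled (linear interpolation) to
#' the force sampling rate so the returned index addresses the force streams.
#'
#' @param position_z vertical position [uniform_series()] (mm).
#' @param force_rate force sampling rate in Hz (default 1000).
#' @param baseline_window index window on the resampled stream; default =
#'   first 200 ms.
#' @param k_sd band width in baseline SDs (default 2).
#' @param min_duration_s sustained duration (default 0.2 s).
#' @return Integer index on the force time base, with the resampled position
#'   as attribute `"resampled"`; errors with class `beadmaze_no_lift` if the
#'   position never stays above the band.
#' @export
find_lift_onset <- function(position_z, force_rate = 1000, baseline_window = NULL,
                            k_sd = 2, min_duration_s = 0.2) {
  pos <- resample_to(position_z, force_rate)
  if (is.null(baseline_window))
    baseline_window <- c(1L, max(2L, round(0.2 * pos$rate)))
  bs <- baseline_stats(pos, baseline_window)
  idx <- sustained_crossing(pos, bs$mean + k_sd * bs$sd, "above", min_duration_s)
  if (is.na(idx))
    stop_beadmaze("no lift detected: position never stayed above baseline + k*SD",
                  "no_lift")
  structure(idx, resampled = pos)
}

#' Compensatory torque at a sample
#'
#' Frontal-plane torque exerted by the digits on the grip device, from the
#' statics of a two-surface precision grip: the normal-force couple acting
#' across the difference in vertical centre-of-pressure heights plus the
#' tangential-force couple acting across the grip width,
#' \deqn{T_{com} = \bar F_n (y_{th} - y_{fi}) + \tfrac{w}{2}(F_{t,th} - F_{t,fi}),}
#' with \eqn{\bar F_n} the mean of the two normal forces at the sample. The
#' sign convention is fixed so that positive torque counters a right-side
#' hidden mass (target +122 N mm).
#'
#' @param trial a [lift_trial()], normally with filtered force streams.
#' @param index sample index (force time base), typically the lift onset.
#' @return Torque in N mm; errors with class `beadmaze_unreliable_contact`
#'   when the mean normal force is at or below 0.1 N (centre of pressure is
#'   then meaningless).
#' @export
compensatory_torque <- function(trial, index) {
  stopifnot(inherits(trial, "lift_trial"))
  n <- length(trial$thumb$fn$values)
  index <- as.integer(index)
  if (is.na(index) || index < 1L || index > n)
    stop_beadmaze("`index` outside the wrench streams", "invalid_index")
  fn_bar <- (trial$thumb$fn$values[index] + trial$fingers$fn$values[index]) / 2
  if (fn_bar <= 0.1)
    stop_beadmaze("mean normal force <= 0.1 N at the requested sample: contact unreliable",
                  "unreliable_contact")
  fn_bar * (trial$thumb$cop_y$values[index] - trial$fingers$cop_y$values[index]) +
    (trial$grip_width_mm / 2) *
      (trial$thumb$ftan$values[index] - trial$fingers$ftan$values[index])
}

#' Target torque for a mass-location condition
#'
#' @param condition `"left"`, `"center"` or `"right"`.
#' @param target_magnitude magnitude of the external torque created by the
#'   hidden 200 g mass; default 122 N mm.
#' @return Signed target torque: +magnitude (right), -magnitude (left), 0
#'   (center).
#' @export
target_torque <- function(condition, target_magnitude = 122) {
  condition <- match.arg(condition, c("left", "center", "right"))
  switch(condition, right = target_magnitude, left = -target_magnitude, center = 0)
}

#' Torque error
#'
#' Absolute difference between the applied compensatory torque at lift onset
#' and the signed target torque required to lift the object without tilt.
#'
#' @param tcom applied compensatory torque (N mm, signed).
#' @param condition mass-location condition.
#' @param target_magnitude see [target_torque()].
#' @return TE in N mm (>= 0).
#' @export
torque_error <- function(tcom, condition, target_magnitude = 122) {
  abs(tcom - target_torque(condition, target_magnitude))
}

#' Per-condition torque-error summary
#'
#' Mean TE over the final 5 trials of a condition's block, after anticipatory
#' scaling has been learned over the block's earlier lifts. Blocks of 10
#' trials are expected; other lengths are flagged.
#'
#' @param te_values numeric vector of per-trial TEs in block order.
#' @param last_n number of final trials to average (default 5).
#' @param expected_block block length under the protocol (default 10).
#' @return List: `mean_te`, `n_trials`, `qc_flags`.
#' @export
condition_te <- function(te_values, last_n = 5L, expected_block = 10L) {
  te_values <- as.numeric(te_values)
  if (length(te_values) < last_n)
    stop_beadmaze(sprintf("need at least %d trials, got %d", last_n, length(te_values)),
                  "too_few_trials")
  qc <- if (length(te_values) != expected_block) "unexpected_block_length" else character()
  list(mean_te = mean(utils::tail(te_values, last_n)),
       n_trials = length(te_values), qc_flags = qc)
}

filter_wrench <- function(w, cutoff_hz, order) {
  digit_wrench(lowpass_zero_phase(w$fn, cutoff_hz, order),
               lowpass_zero_phase(w$ftan, cutoff_hz, order),
               lowpass_zero_phase(w$cop_y, cutoff_hz, order))
}

#' Analyze one lift trial
#'
#' Single-trial chain for the dexterous manipulation task: zero-phase low-pass
#' filtering of the wrench streams, lift-onset detection from the resampled
#' position, compensatory torque at onset, and torque error against the
#' condition's target.
#'
#' @param trial a raw [lift_trial()].
#' @param config list of thresholds, see [default_config()].
#' @return List of class `torque_outcome`: `lift_onset_index`,
#'   `tcom_at_onset`, `te`, `target_torque`, `condition`, `qc_flags`.
#' @export
analyze_lift_trial <- function(trial, config = default_config()) {
  stopifnot(inherits(trial, "lift_trial"))
  filt <- trial
  filt$thumb <- filter_wrench(trial$thumb, config$cutoff_hz, config$filter_order)
  filt$fingers <- filter_wrench(trial$fingers, config$cutoff_hz, config$filter_order)
  qc <- character()
  onset <- tryCatch(
    find_lift_onset(trial$position_z, force_rate = trial$thumb$rate,
                    k_sd = config$k_sd,
                    min_duration_s = config$lift_min_duration_s),
    beadmaze_no_lift = function(e) NA_integer_)
  if (is.na(onset))
    return(structure(list(lift_onset_index = NA_integer_, tcom_at_onset = NA_real_,
                          te = NA_real_, target_torque = target_torque(
                            trial$condition, config$target_torque_nmm),
                          condition = trial$condition,
                          qc_flags = "no_lift_detected"),
                     class = "torque_outcome"))
  onset <- min(as.integer(onset), length(filt$thumb$fn$values))
  tcom <- tryCatch(compensatory_torque(filt, onset),
                   beadmaze_unreliable_contact = function(e) NA_real_)
  if (is.na(tcom)) qc <- c(qc, "unreliable_contact")
  tgt <- target_torque(trial$condition, config$target_torque_nmm)
  structure(list(lift_onset_index = as.integer(onset),
                 tcom_at_onset = tcom,
                 te = if (is.na(tcom)) NA_real_ else abs(tcom - tgt),
                 target_torque = tgt,
                 condition = trial$condition,
                 qc_flags = qc),
            class = "torque_outcome")
}

#' Centre of pressure from a raw 6-axis wrench
#'
#' Convenience conversion for sensors that report moments rather than contact
#' location: the vertical centre-of-pressure coordinate is the moment about
#' the grip-surface horizontal axis divided by the normal force. Samples with
#' normal force below 0.1 N are returned as `NA` (contact unreliable).
#'
#' @param moment_x moment about the horizontal in-surface axis (N mm),
#'   [uniform_series()].
#' @param fn normal force (N), [uniform_series()].
#' @return `uniform_series` of cop_y values (mm), `NA` where fn < 0.1 N.
#' @export
wrench_to_cop <- function(moment_x, fn) {
  stopifnot(inherits(moment_x, "uniform_series"), inherits(fn, "uniform_series"))
  if (length(moment_x$values) != length(fn$values))
    stop_beadmaze("moment and normal-force streams must have equal length", "invalid_wrench")
  v <- moment_x$values / fn$values
  v[fn$values < 0.1] <- NA_real_
  s <- moment_x
  s$values <- v
  s
}
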