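#' Default analysis configuration
#'
#' All thresholds default to the protocol's values: detection bands of
#' mean +/- 2 SD, a 10 ms sustained rule for trial start, a 200 ms sustained
#' rule for lift onset, the -0.2 N y-force end threshold, a 30 Hz / 5th-order
#' zero-phase Butterworth filter, the 122 N mm target torque magnitude, a
#' 75/25 stratified split and 5-fold cross-validation. The baseline window
#' (unspecified by the protocol) defaults to the first 200 ms of each
#' recording.
#'
#' @return Named list of settings.
#' @export
default_config <- function() {
  list(cutoff_hz = 30,
       filter_order = 5L,
       k_sd = 2,
       start_min_duration_s = 0.010,
       lift_min_duration_s = 0.200,
       end_threshold_n = -0.2,
       target_torque_nmm = 122,
       baseline_window_s = 0.2,
       baseline_on = "raw",
       two_sided_start = TRUE,
       test_fraction = 0.25,
       stratify_on = "gender",
       cv_folds = 5L,
       lambda_grid = default_lambda_grid(),
       alpha = 0.05,
       condition_last_n = 5L,
       trials_per_block = 10L,
       bmhft_trials = 5L)
}

#' Fingerprint of a configuration
#'
#' MD5 of the canonical JSON serialization, logged with every model report so
#' that runs are attributable to an exact parameterization.
#'
#' @param config a configuration list.
#' @return Character MD5 string.
#' @export
config_fingerprint <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

write_delim_exact <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- fmt_num(df[[j]])
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
}

read_delim_checked <- function(path, required, what) {
  if (!file.exists(path))
    stop_beadmaze(sprintf("cannot read %s file '%s': no such file", what, path),
                  "unreadable_file")
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop_beadmaze(sprintf("malformed %s file '%s': missing column(s) %s", what,
                          path, paste(missing, collapse = ", ")),
                  "bad_header")
  df
}

validate_time_column <- function(t, path) {
  if (length(t) < 2L || any(diff(t) <= 0))
    stop_beadmaze(sprintf("file '%s': time column must be strictly increasing", path),
                  "bad_time")
  dt <- diff(t)
  if (max(abs(dt - mean(dt))) > 1e-6 * mean(dt))
    stop_beadmaze(sprintf("file '%s': time step is not constant (rel tol 1e-6)", path),
                  "bad_time")
  1 / mean(dt)
}

#' Write / read a uniform series as delimited text
#'
#' Dialect: header `t,<channel>`, comma-separated, time strictly increasing
#' with a constant step (validated on read to 1e-6 relative tolerance).
#' Values are written with 17 significant digits so a write/read round trip
#' is exact to double precision.
#'
#' @param series a [uniform_series()].
#' @param path file path.
#' @param channel column name for the values.
#' @return `write_series` returns `path` invisibly; `read_series` returns a
#'   `uniform_series`.
#' @export
write_series <- function(series, path, channel = "value") {
  df <- data.frame(t = series_times(series), v = series$values)
  names(df)[2] <- channel
  write_delim_exact(df, path)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path, channel = NULL) {
  df <- read_delim_checked(path, "t", "series")
  if (is.null(channel)) channel <- setdiff(names(df), "t")[1]
  if (!channel %in% names(df))
    stop_beadmaze(sprintf("file '%s' has no column '%s'", path, channel), "bad_header")
  rate <- validate_time_column(df$t, path)
  uniform_series(df[[channel]], rate, t0 = df$t[1])
}

#' Write / read a triaxial force trace
#'
#' Dialect: `t,fx,fy,fz` delimited text.
#'
#' @param trace a [force_trace()].
#' @param path file path.
#' @param subject_id,trial_id,wire_shape identifiers applied on read.
#' @return `write_trace` returns `path` invisibly; `read_trace` a
#'   `force_trace`.
#' @export
write_trace <- function(trace, path) {
  write_delim_exact(data.frame(t = series_times(trace$fx),
                               fx = trace$fx$values, fy = trace$fy$values,
                               fz = trace$fz$values), path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, subject_id = NA_character_, trial_id = NA_integer_,
                       wire_shape = "double_curve") {
  df <- read_delim_checked(path, c("t", "fx", "fy", "fz"), "trace")
  rate <- validate_time_column(df$t, path)
  force_trace(df$fx, df$fy, df$fz, rate = rate, subject_id = subject_id,
              trial_id = trial_id, wire_shape = wire_shape)
}

#' Write / read a lift trial's stream files
#'
#' A lift trial is stored as a pair of files: a wrench file
#' `t,fn_th,ftan_th,copy_th,fn_in,ftan_in,copy_in` at the force rate and a
#' position file `t,z` at the position rate. Condition and grip width travel
#' in a per-trial metadata table (see [write_lift_metadata()]).
#'
#' @param trial a [lift_trial()].
#' @param wrench_path,position_path file paths.
#' @return `write_lift_trial` returns the paths invisibly; `read_lift_trial`
#'   a `lift_trial`.
#' @export
write_lift_trial <- function(trial, wrench_path, position_path) {
  write_delim_exact(data.frame(t = series_times(trial$thumb$fn),
                               fn_th = trial$thumb$fn$values,
                               ftan_th = trial$thumb$ftan$values,
                               copy_th = trial$thumb$cop_y$values,
                               fn_in = trial$fingers$fn$values,
                               ftan_in = trial$fingers$ftan$values,
                               copy_in = trial$fingers$cop_y$values),
                    wrench_path)
  write_delim_exact(data.frame(t = series_times(trial$position_z),
                               z = trial$position_z$values), position_path)
  invisible(c(wrench_path, position_path))
}

#' @rdname write_lift_trial
#' @param condition,grip_width_mm trial metadata applied on read.
#' @export
read_lift_trial <- function(wrench_path, position_path, condition,
                            grip_width_mm = 50) {
  w <- read_delim_checked(wrench_path,
                          c("t", "fn_th", "ftan_th", "copy_th", "fn_in",
                            "ftan_in", "copy_in"), "wrench")
  rate <- validate_time_column(w$t, wrench_path)
  p <- read_delim_checked(position_path, c("t", "z"), "position")
  prate <- validate_time_column(p$t, position_path)
  lift_trial(digit_wrench(w$fn_th, w$ftan_th, w$copy_th, rate = rate),
             digit_wrench(w$fn_in, w$ftan_in, w$copy_in, rate = rate),
             uniform_series(p$z, prate, t0 = p$t[1]),
             condition = condition, grip_width_mm = grip_width_mm)
}

#' Write / read the per-trial lift metadata sidecar
#'
#' Columns: `subject,condition,block,trial,wrench_file,position_file`.
#'
#' @param meta data frame with those columns.
#' @param path file path.
#' @return `read_lift_metadata` returns the data frame.
#' @export
write_lift_metadata <- function(meta, path) {
  write_delim_exact(meta, path)
  invisible(path)
}

#' @rdname write_lift_metadata
#' @export
read_lift_metadata <- function(path) {
  read_delim_checked(path, c("subject", "condition", "block", "trial",
                             "wrench_file", "position_file"), "lift metadata")
}

#' Write / read a cohort table
#'
#' One row per subject: `subject_id`, the nine features of
#' [cohort_features()] and the `total_force` outcome.
#'
#' @param cohort data frame.
#' @param path file path.
#' @return `read_cohort` returns the data frame.
#' @export
write_cohort <- function(cohort, path) {
  write_delim_exact(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  read_delim_checked(path, c(cohort_features(), "total_force"), "cohort")
}

#' Write / read a model report as JSON
#'
#' Serializes a `model_report` (see [run_cohort_model()]) to structured JSON
#' with full numeric precision. No timestamps are written, so reports from
#' identical configurations and seeds are byte-identical.
#'
#' @param report a `model_report`.
#' @param path file path.
#' @return `read_model_report` returns the parsed list.
#' @export
write_model_report <- function(report, path) {
  out <- list(
    lambda = report$lambda,
    coefficients = as.list(report$coefficients),
    intercept = report$intercept,
    r2_train = report$r2_train, r2_test = report$r2_test,
    aic = report$aic, bic = report$bic,
    n_train = report$n_train, n_test = report$n_test,
    mean_abs_shap = as.list(report$mean_abs_shap),
    ranking = report$ranking,
    base_value = report$base_value,
    shap_values = report$shap_values,
    spearman = report$spearman,
    split_seed = report$split_seed, cv_folds = report$cv_folds,
    lambda_grid = report$lambda_grid,
    config_fingerprint = report$config_fingerprint)
  writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns", na = "null"), path)
  invisible(path)
}

#' @rdname write_model_report
#' @export
read_model_report <- function(path) {
  jsonlite::fromJSON(path)
}
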