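#' @title Synthetic-data generators
#' @description Seeded generators emulating the study's raw inputs: BMHFT
#'   force traces with planted contact and end events, grip-and-lift blocks
#'   with a planted torque-learning trajectory, and a correlated 9-feature
#'   cohort with a known linear effect structure on total force. Their
#'   purpose is to make every pipeline stage testable against known ground
#'   truth; they are not biomechanical simulations.
#' @name synthetic-data
NULL

# smooth 0 -> 1 half-cosine edge over u in [0, 1]
cos_edge <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  (1 - cos(pi * u)) / 2
}

#' Specification of a synthetic BMHFT trace
#'
#' @param rate sampling rate (Hz), default 1000.
#' @param duration_s total recording length (s).
#' @param start_time_s nominal bead-contact time (s); the traversal force
#'   rise begins here.
#' @param end_time_s time at which the planted y-force descent crosses
#'   -0.2 N (the bead reaching the stationary bead).
#' @param amplitude peak traversal force (N) on the strongest channel; must
#'   exceed twice the largest baseline SD or the spec is refused (the planted
#'   event could never trigger detection).
#' @param baseline_sd named Gaussian noise SD per channel (N).
#' @param end_depth depth of the end-event drop (N); must be <= -0.2.
#' @param rise_s duration of the contact force rise (s).
#' @param seed integer seed.
#' @return List of class `trace_spec`.
#' @export
trace_spec <- function(rate = 1000, duration_s = 6, start_time_s = 1.5,
                       end_time_s = 4.2, amplitude = 0.8,
                       baseline_sd = c(fx = 0.01, fy = 0.01, fz = 0.01),
                       end_depth = -0.45, rise_s = 0.04, seed = 1L) {
  if (end_time_s <= start_time_s)
    stop_beadmaze("end_time_s must exceed start_time_s", "invalid_spec")
  if (end_depth > -0.2)
    stop_beadmaze("end_depth must be <= -0.2 N so the end rule can trigger", "invalid_spec")
  if (duration_s < end_time_s + 0.5)
    stop_beadmaze("duration_s must leave >= 0.5 s after the end event", "invalid_spec")
  if (start_time_s < 0.5)
    stop_beadmaze("start_time_s must leave >= 0.5 s of baseline", "invalid_spec")
  if (amplitude < 2 * max(baseline_sd))
    stop_beadmaze("refused: amplitude below 2 x baseline SD can never trigger detection",
                  "undetectable_spec")
  structure(list(rate = rate, duration_s = duration_s, start_time_s = start_time_s,
                 end_time_s = end_time_s, amplitude = amplitude,
                 baseline_sd = baseline_sd, end_depth = end_depth,
                 rise_s = rise_s, seed = as.integer(seed)),
            class = "trace_spec")
}

# noiseless channel profiles for a trace spec; returns list(fx, fy, fz)
bmhft_clean_profiles <- function(spec) {
  t <- (seq_len(round(spec$duration_s * spec$rate)) - 1) / spec$rate
  amp <- spec$amplitude * c(fx = 0.75, fy = 0.6, fz = 1.0)
  seg <- spec$end_time_s - spec$start_time_s
  # two low-frequency undulations: the double-curve wire's two direction changes
  shape <- 0.7 + 0.15 * cos(2 * pi * 1.1 * (t - spec$start_time_s)) +
    0.15 * cos(2 * pi * 0.6 * (t - spec$start_time_s) + 1)
  env_in <- cos_edge((t - spec$start_time_s) / spec$rise_s)
  env_out <- 1 - cos_edge((t - spec$end_time_s - 0.10) / 0.15)  # grasp release
  trav <- function(a) a * env_in * shape * env_out
  fx <- trav(amp[["fx"]])
  fz <- trav(amp[["fz"]])
  fy <- trav(amp[["fy"]])
  # end event: linear descent at `slope` N/s crossing -0.2 N exactly at end_time_s,
  # clamped at end_depth, held 0.15 s, then released back to zero
  slope <- 30
  desc <- -0.2 - slope * (t - spec$end_time_s)
  hold_end <- spec$end_time_s + (abs(spec$end_depth) - 0.2) / slope + 0.15
  desc <- pmax(desc, spec$end_depth)
  in_desc <- t >= spec$end_time_s - 2 & t <= hold_end
  fy[in_desc] <- pmin(fy[in_desc], desc[in_desc])
  rel <- t > hold_end
  fy[rel] <- spec$end_depth * (1 - cos_edge((t[rel] - hold_end) / 0.1))
  list(fx = fx, fy = fy, fz = fz)
}

#' Generate a synthetic BMHFT force trace with planted events
#'
#' Builds noiseless traversal profiles (smooth low-frequency content, a fast
#' contact rise at `start_time_s`, and a steep y-force descent through
#' -0.2 N at `end_time_s`), adds white Gaussian baseline noise, and returns
#' the trace together with the planted ground-truth segment.
#'
#' The planted start index is defined on the noiseless signal as seen through
#' the standard measurement chain: the first sustained (10 ms) exceedance of
#' the filtered clean profile over the nominal detection band `2 sd` — the
#' same band the pipeline estimates, in expectation, from the raw baseline
#' (see [score_bmhft_trial()]). The planted end index is the first filtered
#' clean `fy <= -0.2 N` after the start. Recovery of these indices from the
#' noisy trace therefore measures the detectors' noise robustness.
#'
#' @param spec a [trace_spec()].
#' @param subject_id,trial_id identifiers stamped on the trace.
#' @param config filter settings used for the planted truth (see
#'   [default_config()]); use the same config when scoring.
#' @return List: `trace` (a [force_trace()]), `truth` (a [trial_segment()]),
#'   `clean` (list of noiseless channel vectors).
#' @export
gen_bmhft_trace <- function(spec, subject_id = "S01", trial_id = 1L,
                            config = default_config()) {
  stopifnot(inherits(spec, "trace_spec"))
  clean <- bmhft_clean_profiles(spec)
  filt <- lapply(clean, function(v)
    lowpass_zero_phase(uniform_series(v, spec$rate), config$cutoff_hz,
                       config$filter_order))
  starts <- vapply(c("fx", "fy", "fz"), function(ch) {
    sd_ch <- spec$baseline_sd[[ch]]
    sustained_crossing(uniform_series(abs(filt[[ch]]$values), spec$rate),
                       config$k_sd * sd_ch, "above",
                       config$start_min_duration_s)
  }, integer(1))
  if (all(is.na(starts)))
    stop_beadmaze("refused: planted profile never leaves the nominal detection band",
                  "undetectable_spec")
  start_truth <- min(starts, na.rm = TRUE)
  after <- which(filt$fy$values[(start_truth + 1L):length(filt$fy$values)] <=
                   config$end_threshold_n)
  if (length(after) == 0L)
    stop_beadmaze("refused: planted fy never reaches the end threshold", "undetectable_spec")
  end_truth <- start_truth + after[1L]
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))
  noisy <- lapply(c(fx = "fx", fy = "fy", fz = "fz"), function(ch)
    clean[[ch]] + stats::rnorm(length(clean[[ch]]), 0, spec$baseline_sd[[ch]]))
  list(trace = force_trace(noisy$fx, noisy$fy, noisy$fz, rate = spec$rate,
                           subject_id = subject_id, trial_id = trial_id),
       truth = trial_segment(start_truth, end_truth, spec$rate),
       clean = clean)
}

#' Specification of a synthetic grip-and-lift block
#'
#' @param condition hidden-mass location (`"left"`, `"center"`, `"right"`).
#' @param learning_rate per-trial convergence rate `r` in `[0, 1]`: the
#'   planted compensatory torque on trial `i` is
#'   `asymptote (1 - (1-r)^i) + eps_i`.
#' @param noise_sd SD of the per-trial torque noise `eps` (N mm).
#' @param trials_per_block trials in the block (default 10, protocol value;
#'   must be >= 5).
#' @param onset_time_s planted lift-onset time (s).
#' @param duration_s trial length (s).
#' @param rate force sampling rate (Hz).
#' @param position_rate position sampling rate (Hz), default 120.
#' @param position_noise_sd_mm baseline position noise SD (mm); default 0
#'   (the planted trajectory is the noise model's mean — per-trial variability
#'   enters through the torque noise, not the kinematics). With nonzero noise
#'   the onset band self-calibrates to it, and detection can only be localized
#'   to the 120 Hz sample grid.
#' @param grip_width_mm grip aperture (mm), default 50.
#' @param target_magnitude external torque magnitude (N mm), default 122.
#' @param asymptote steady-state planted torque (N mm); default = the signed
#'   condition target, i.e. perfect asymptotic anticipation. Setting it off
#'   target plants a persistent torque error.
#' @param grip_force_n plateau normal force per digit (N).
#' @param load_n total vertical load supported (N); default 4.14 (the 421.9 g
#'   device).
#' @param seed integer seed.
#' @return List of class `lift_spec`.
#' @export
lift_spec <- function(condition = "right", learning_rate = 0.65, noise_sd = 8,
                      trials_per_block = 10L, onset_time_s = 1.2,
                      duration_s = 2.6, rate = 1000, position_rate = 120,
                      position_noise_sd_mm = 0, grip_width_mm = 50,
                      target_magnitude = 122, asymptote = NULL,
                      grip_force_n = 10, load_n = 4.14, seed = 1L) {
  condition <- match.arg(condition, c("left", "center", "right"))
  if (learning_rate < 0 || learning_rate > 1)
    stop_beadmaze("learning_rate must lie in [0, 1]", "invalid_spec")
  if (trials_per_block < 5L)
    stop_beadmaze("a block needs at least 5 trials", "invalid_spec")
  if (onset_time_s < 0.7 || onset_time_s > duration_s - 1.2)
    stop_beadmaze("onset_time_s must leave room for baseline and the sustained rise",
                  "invalid_spec")
  tgt <- target_torque(condition, target_magnitude)
  structure(list(condition = condition, learning_rate = learning_rate,
                 noise_sd = noise_sd, trials_per_block = as.integer(trials_per_block),
                 onset_time_s = onset_time_s, duration_s = duration_s,
                 rate = rate, position_rate = position_rate,
                 position_noise_sd_mm = position_noise_sd_mm,
                 grip_width_mm = grip_width_mm,
                 target_magnitude = target_magnitude, target = tgt,
                 asymptote = if (is.null(asymptote)) tgt else asymptote,
                 grip_force_n = grip_force_n, load_n = load_n,
                 seed = as.integer(seed)),
            class = "lift_spec")
}

# one trial's streams carrying an exactly planted torque at the hold plateau
lift_trial_streams <- function(spec, tcom) {
  n <- round(spec$duration_s * spec$rate)
  t <- (seq_len(n) - 1) / spec$rate
  ramp <- cos_edge((t - 0.3) / 0.3)        # contact force rise 0.3-0.6 s
  f0 <- spec$grip_force_n
  w2 <- spec$grip_width_mm / 2
  # split the planted torque between the CoP couple and the tangential couple
  d_cop <- 0.3 * tcom / f0                  # cop height difference (mm)
  d_tan <- 0.7 * tcom / w2                  # tangential force difference (N)
  fn <- f0 * ramp
  th <- digit_wrench(fn,
                     (spec$load_n / 2 + d_tan / 2) * ramp,
                     rep(d_cop / 2, n), rate = spec$rate)
  fi <- digit_wrench(fn,
                     (spec$load_n / 2 - d_tan / 2) * ramp,
                     rep(-d_cop / 2, n), rate = spec$rate)
  np <- round(spec$duration_s * spec$position_rate)
  tp <- (seq_len(np) - 1) / spec$position_rate
  # quarter-sine rise to 100 mm over 1 s: steep initial slope so the planted
  # onset is sharply defined against the 2 SD position band
  u <- pmin(pmax((tp - spec$onset_time_s) / 1.0, 0), 1)
  pos_clean <- 100 * sin(pi * u / 2)
  list(thumb = th, fingers = fi, pos_clean = pos_clean, pos_times = tp)
}

#' Generate a synthetic grip-and-lift block with a planted learning curve
#'
#' Trial `i` (1-based) of the block carries planted compensatory torque
#' `tcom_i = asymptote (1 - (1-r)^i) + eps_i`. Wrench streams are noiseless
#' and constant around the lift so that [compensatory_torque()] at the
#' planted onset recovers `tcom_i` to numerical precision even after
#' filtering; trial-to-trial variability enters through the torque noise
#' `eps`. The planted onset index is the first sustained (200 ms) exceedance
#' of the noiseless resampled position over the nominal band `2 sd_pos`
#' (the strict zero threshold when the position stream is noiseless).
#'
#' @param spec a [lift_spec()].
#' @return List: `trials` (list of [lift_trial()]), `planted` (data frame
#'   with `trial`, `tcom`, `te`, `onset_index`), `target` (signed N mm).
#' @export
gen_lift_block <- function(spec) {
  stopifnot(inherits(spec, "lift_spec"))
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))
  i <- seq_len(spec$trials_per_block)
  eps <- stats::rnorm(spec$trials_per_block, 0, spec$noise_sd)
  tcom <- spec$asymptote * (1 - (1 - spec$learning_rate)^i) + eps
  trials <- vector("list", spec$trials_per_block)
  onset_idx <- integer(spec$trials_per_block)
  for (k in i) {
    s <- lift_trial_streams(spec, tcom[k])
    pos_clean <- uniform_series(s$pos_clean, spec$position_rate)
    planted <- sustained_crossing(resample_to(pos_clean, spec$rate),
                                  2 * spec$position_noise_sd_mm, "above", 0.2)
    onset_idx[k] <- planted
    pos <- uniform_series(
      s$pos_clean + stats::rnorm(length(s$pos_clean), 0, spec$position_noise_sd_mm),
      spec$position_rate)
    trials[[k]] <- lift_trial(s$thumb, s$fingers, pos, spec$condition,
                              spec$grip_width_mm)
  }
  list(trials = trials,
       planted = data.frame(trial = i, tcom = tcom,
                            te = abs(tcom - spec$target),
                            onset_index = onset_idx),
       target = spec$target)
}

#' Default latent correlation among the continuous features
#'
#' Correlation of the latent residuals (conditional on age and gender) of the
#' seven continuous features. Hand size and strength measures are mutually
#' positively correlated (the collinearity motivating the ridge model);
#' stereognosis is weakly related; the two torque errors share subject-level
#' anticipatory skill.
#'
#' @return 7 x 7 positive-definite correlation matrix.
#' @export
default_latent_cor <- function() {
  nm <- c("hand_span", "hand_length", "pinch_strength", "key_strength",
          "stereognosis", "r_te", "l_te")
  R <- diag(7)
  dimnames(R) <- list(nm, nm)
  set_pair <- function(a, b, v) {
    R[a, b] <<- v; R[b, a] <<- v
  }
  set_pair("hand_span", "hand_length", 0.70)
  set_pair("hand_span", "pinch_strength", 0.45)
  set_pair("hand_span", "key_strength", 0.45)
  set_pair("hand_length", "pinch_strength", 0.45)
  set_pair("hand_length", "key_strength", 0.45)
  set_pair("pinch_strength", "key_strength", 0.60)
  for (f in c("hand_span", "hand_length", "pinch_strength", "key_strength"))
    set_pair("stereognosis", f, 0.10)
  set_pair("r_te", "l_te", 0.45)
  R
}

#' Default planted effect vector
#'
#' Per-SD effects on total force mirroring the study design's qualitative
#' structure: worse right-condition anticipation raises total force; female
#' gender, older age and stronger pinch lower it; the remaining features are
#' null. Illustrative, not an estimate of any real dataset.
#'
#' @return Named numeric vector over [cohort_features()].
#' @export
default_effects <- function() {
  c(age = -22, gender = -40, hand_span = 0, hand_length = 0,
    pinch_strength = -12, key_strength = 0, stereognosis = 0,
    r_te = 60, l_te = 0)
}

#' Correlation of the standardized 9-feature recovery design
#'
#' Joint correlation used by the generator's `standardized` mode: the latent
#' structure of [default_latent_cor()] among the seven continuous features,
#' age moderately correlated with hand size and strength (developmental
#' trend) and negatively with the torque errors, gender independent.
#'
#' @return 9 x 9 positive-definite correlation matrix over
#'   [cohort_features()].
#' @export
default_standardized_cor <- function() {
  nm <- cohort_features()
  R <- diag(9)
  dimnames(R) <- list(nm, nm)
  R7 <- default_latent_cor()
  R[rownames(R7), colnames(R7)] <- R7
  for (f in c("hand_span", "hand_length", "pinch_strength", "key_strength")) {
    R["age", f] <- R[f, "age"] <- 0.5
  }
  R["age", "stereognosis"] <- R["stereognosis", "age"] <- 0.15
  R["age", "r_te"] <- R["r_te", "age"] <- -0.35
  R["age", "l_te"] <- R["l_te", "age"] <- -0.35
  R
}

#' Specification of a synthetic cohort
#'
#' @param n subjects (>= 8).
#' @param age_bands list of `c(lo, hi)` year ranges; default the study's two
#'   recruitment bands, 5-10 and 15-17 years.
#' @param band_weights sampling weights of the bands; default 28:11.
#' @param female_prob probability of gender = 1 (female).
#' @param latent_cor correlation of the continuous features' latent residuals
#'   (positive definite; checked).
#' @param beta named per-SD effect vector on the standardized features.
#' @param intercept mean total force (raw L1 per-sample sum units).
#' @param noise_sd residual SD of total force.
#' @param standardized if `TRUE`, generate the abstract recovery design
#'   instead of the realistic cohort: all nine features jointly Gaussian,
#'   pre-standardized, correlated by [default_standardized_cor()]. Used to
#'   verify parameter recovery where planted effects must be identifiable;
#'   the realistic mode's near-collinear age trends make small individual
#'   effects within the hand-size/strength block unidentifiable at any
#'   sample size a study would run.
#' @param seed integer seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 39, age_bands = list(c(5, 10), c(15, 17)),
                        band_weights = c(28, 11), female_prob = 0.5,
                        latent_cor = default_latent_cor(),
                        beta = default_effects(), intercept = 2000,
                        noise_sd = 100, standardized = FALSE, seed = 1L) {
  if (n < 8L) stop_beadmaze("need n >= 8 subjects", "invalid_spec")
  ev <- eigen(latent_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop_beadmaze("latent correlation matrix is not positive definite", "invalid_spec")
  if (!all(cohort_features() %in% names(beta)))
    stop_beadmaze("`beta` must name all nine model features", "invalid_spec")
  structure(list(n = as.integer(n), age_bands = age_bands,
                 band_weights = band_weights, female_prob = female_prob,
                 latent_cor = latent_cor, beta = beta[cohort_features()],
                 intercept = intercept, noise_sd = noise_sd,
                 standardized = isTRUE(standardized),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort table
#'
#' Draws gender (Bernoulli) and age (uniform within the weighted recruitment
#' bands); builds the continuous features as age/gender-conditional means
#' plus correlated Gaussian latent residuals (so hand size and strength rise
#' with age, creating the marginal collinearity the model is designed for);
#' rounds stereognosis to an integer clamped to 0-9; and sets the outcome to
#' `intercept + beta . z(features) + noise` with population-z-scored features.
#'
#' @param spec a [cohort_spec()].
#' @return List: `cohort` (data frame, one row per subject, columns
#'   `subject_id`, the nine features and `total_force`), `meta` (list with
#'   the true `beta`, the latent residual matrix, the z-scored design and the
#'   seed).
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))
  n <- spec$n
  if (spec$standardized) {
    R9 <- default_standardized_cor()
    F9 <- matrix(stats::rnorm(n * 9), n, 9) %*% chol(R9)
    colnames(F9) <- cohort_features()
    cohort <- data.frame(subject_id = sprintf("S%04d", seq_len(n)), F9)
    Z <- vapply(cohort_features(), function(f) {
      x <- cohort[[f]]
      (x - mean(x)) / sqrt(mean((x - mean(x))^2))
    }, numeric(n))
    cohort$total_force <- spec$intercept + drop(Z %*% spec$beta) +
      stats::rnorm(n, 0, spec$noise_sd)
    return(list(cohort = cohort,
                meta = list(beta = spec$beta, latents = F9, design_z = Z,
                            seed = spec$seed)))
  }
  band <- sample(seq_along(spec$age_bands), n, replace = TRUE,
                 prob = spec$band_weights)
  age <- vapply(band, function(b)
    stats::runif(1, spec$age_bands[[b]][1], spec$age_bands[[b]][2]), numeric(1))
  gender <- stats::rbinom(n, 1, spec$female_prob)
  E <- matrix(stats::rnorm(n * 7), n, 7) %*% chol(spec$latent_cor)
  colnames(E) <- colnames(spec$latent_cor)
  a <- age - 10
  cohort <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    age = round(age, 1),
    gender = gender,
    hand_span = 14 + 0.45 * a - 0.3 * gender + 1.0 * E[, "hand_span"],
    hand_length = 15.5 + 0.5 * a - 0.3 * gender + 1.0 * E[, "hand_length"],
    pinch_strength = pmax(0.5, 4.5 + 0.35 * a - 0.3 * gender +
                            0.8 * E[, "pinch_strength"]),
    key_strength = pmax(0.5, 6 + 0.45 * a - 0.3 * gender +
                          1.0 * E[, "key_strength"]),
    stereognosis = pmin(9L, pmax(0L, as.integer(round(
      7.3 + 0.14 * a + 1.0 * E[, "stereognosis"])))),
    r_te = pmax(1, 45 - 2.2 * a - 3 * gender + 12 * E[, "r_te"]),
    l_te = pmax(1, 35 - 1.8 * a - 2 * gender + 10 * E[, "l_te"])
  )
  Z <- vapply(cohort_features(), function(f) {
    x <- cohort[[f]]
    (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  }, numeric(n))
  cohort$total_force <- spec$intercept + drop(Z %*% spec$beta) +
    stats::rnorm(n, 0, spec$noise_sd)
  list(cohort = cohort,
       meta = list(beta = spec$beta, latents = E, design_z = Z,
                   seed = spec$seed))
}
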