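#' Per-subject seed table for a synthetic study
#'
#' Derives one row of independent sub-seeds per subject from a single master
#' seed, so that every simulation stage (BMHFT trials, the three lift-block
#' conditions) is reproducible independently of the order in which stages
#' are run. Used by [run_report()] and the analysis scripts.
#'
#' @param n_subjects number of subjects.
#' @param seed integer master seed.
#' @return Integer matrix, `n_subjects` x 8; column 1 seeds the BMHFT
#'   trials, columns 2-4 the right/left/center lift blocks.
#' @export
study_seeds <- function(n_subjects, seed) {
  old <- local_seed(as.integer(seed))
  on.exit(restore_seed(old))
  matrix(sample.int(.Machine$integer.max - 1L, n_subjects * 8L),
         nrow = n_subjects)
}

#' End-to-end synthetic study run
#'
#' Runs the entire analysis chain on a synthetic cohort, from raw signals to
#' the fitted model: (1) generate a cohort with planted effect structure;
#' (2) for every subject, synthesize five BMHFT force traces whose planted
#' amplitude encodes the subject's outcome, then segment and score them from
#' the noisy signals; (3) synthesize grip-and-lift blocks (10 trials per
#' mass-location condition) whose planted steady-state torque error encodes
#' the subject's anticipatory skill, then recover lift onsets, compensatory
#' torques and last-5-trial TEs from the streams; (4) assemble the measured
#' cohort table and fit the standardized cross-validated ridge model with
#' SHAP attributions and the Spearman/Bonferroni screen.
#'
#' Every random draw is controlled by `seed`; two runs with the same seed and
#' configuration produce byte-identical outputs.
#'
#' @param n_subjects cohort size (default 39).
#' @param config settings list, see [default_config()].
#' @param seed integer master seed.
#' @param out_dir optional directory; when given, writes `cohort.csv`,
#'   `bmhft_scores.csv`, `torque_outcomes.csv` and `model_report.json` there.
#' @param lift_noise_sd per-trial torque noise for the synthetic lift blocks
#'   (N mm).
#' @param learning_rate planted per-trial torque convergence rate.
#' @return List: `planted` (generator output), `cohort` (measured table),
#'   `bmhft_scores` (per-trial rows), `torque_outcomes` (per-trial rows),
#'   `report` (the `model_report`).
#' @export
run_report <- function(n_subjects = 39, config = default_config(), seed = 1L,
                       out_dir = NULL, lift_noise_sd = 8, learning_rate = 0.65) {
  seed <- as.integer(seed)
  sub_seeds <- study_seeds(n_subjects, seed)

  gc <- gen_cohort(cohort_spec(n = n_subjects, seed = seed))
  planted <- gc$cohort

  # calibration: L1 sum of the unit-amplitude clean profile over its planted
  # segment, so a subject's planted outcome maps to a trace amplitude
  ref <- gen_bmhft_trace(trace_spec(amplitude = 1, seed = 1L), config = config)
  w <- ref$truth$start_index:ref$truth$end_index
  unit_l1 <- sum(abs(ref$clean$fx[w]) + abs(ref$clean$fy[w]) + abs(ref$clean$fz[w]))

  score_rows <- list()
  te_rows <- list()
  measured_tf <- measured_rte <- measured_lte <- numeric(n_subjects)
  conditions <- c("right", "left", "center")

  for (s in seq_len(n_subjects)) {
    sid <- planted$subject_id[s]
    amp <- planted$total_force[s] / unit_l1
    trial_scores <- vector("list", config$bmhft_trials)
    for (k in seq_len(config$bmhft_trials)) {
      tr <- gen_bmhft_trace(trace_spec(amplitude = amp,
                                       seed = sub_seeds[s, 1] + k),
                            subject_id = sid, trial_id = k, config = config)
      res <- score_bmhft_trial(tr$trace, config)
      trial_scores[[k]] <- res$score
      score_rows[[length(score_rows) + 1L]] <- data.frame(
        subject = sid, trial = k,
        start_s = if (is.null(res$segment)) NA_real_ else
          (res$segment$start_index - 1) / tr$trace$rate,
        end_s = if (is.null(res$segment)) NA_real_ else
          (res$segment$end_index - 1) / tr$trace$rate,
        duration_s = if (is.null(res$segment)) NA_real_ else res$segment$duration_s,
        total_force = if (is.null(res$score)) NA_real_ else res$score$total_force,
        total_force_integral = if (is.null(res$score)) NA_real_ else
          res$score$total_force_integral,
        qc_flags = paste(res$qc_flags, collapse = ";"))
    }
    measured_tf[s] <- score_subject(trial_scores, config$bmhft_trials)$mean_total_force

    for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      tgt <- target_torque(cond, config$target_torque_nmm)
      te_planted <- switch(cond, right = planted$r_te[s], left = planted$l_te[s],
                           center = 0)
      spec <- lift_spec(condition = cond, learning_rate = learning_rate,
                        noise_sd = lift_noise_sd,
                        trials_per_block = config$trials_per_block,
                        target_magnitude = config$target_torque_nmm,
                        asymptote = tgt - sign(tgt) * te_planted,
                        seed = sub_seeds[s, 1 + ci])
      block <- gen_lift_block(spec)
      tes <- numeric(length(block$trials))
      for (k in seq_along(block$trials)) {
        out <- analyze_lift_trial(block$trials[[k]], config)
        tes[k] <- out$te
        te_rows[[length(te_rows) + 1L]] <- data.frame(
          subject = sid, condition = cond, trial = k,
          lift_onset_s = if (is.na(out$lift_onset_index)) NA_real_ else
            (out$lift_onset_index - 1) / spec$rate,
          tcom_nmm = out$tcom_at_onset, te_nmm = out$te,
          target_nmm = out$target_torque,
          qc_flags = paste(out$qc_flags, collapse = ";"))
      }
      mte <- condition_te(tes, config$condition_last_n, config$trials_per_block)$mean_te
      if (cond == "right") measured_rte[s] <- mte
      if (cond == "left") measured_lte[s] <- mte
    }
  }

  cohort <- planted
  cohort$r_te <- measured_rte
  cohort$l_te <- measured_lte
  cohort$total_force <- measured_tf

  report <- run_cohort_model(cohort, config, seed)
  bmhft_scores <- do.call(rbind, score_rows)
  torque_outcomes <- do.call(rbind, te_rows)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    write_delim_exact(bmhft_scores, file.path(out_dir, "bmhft_scores.csv"))
    write_delim_exact(torque_outcomes, file.path(out_dir, "torque_outcomes.csv"))
    write_model_report(report, file.path(out_dir, "model_report.json"))
  }

  list(planted = gc, cohort = cohort, bmhft_scores = bmhft_scores,
       torque_outcomes = torque_outcomes, report = report)
}
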