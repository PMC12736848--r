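#!/usr/bin/env Rscript
# Stage 3 — torque error on the dexterous manipulation task.
#
# For every subject and mass-location condition (right, left, center), a
# 10-trial lift block is regenerated from the master seed. Each trial's
# wrench streams are filtered, lift onset is detected from the resampled
# vertical position (mean + 2 SD sustained 200 ms), compensatory torque is
# computed at onset, and TE is its absolute deviation from the +/-122 N mm
# condition target. The subject's condition TE is the mean over the block's
# last five trials, after anticipatory scaling has been learned.

suppressPackageStartupMessages(library(beadmaze))
seed <- 1L
cfg <- default_config()
dir.create("results", showWarnings = FALSE)

planted <- read_cohort("results/planted_cohort.csv")
seeds <- study_seeds(nrow(planted), seed)
conditions <- c("right", "left", "center")

rows <- list(); subj <- list()
for (s in seq_len(nrow(planted))) {
  sid <- planted$subject_id[s]
  te_by_cond <- c(right = NA_real_, left = NA_real_, center = NA_real_)
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    tgt <- target_torque(cond, cfg$target_torque_nmm)
    te_planted <- switch(cond, right = planted$r_te[s], left = planted$l_te[s],
                         center = 0)
    blk <- gen_lift_block(lift_spec(condition = cond, learning_rate = 0.65,
                                    noise_sd = 8,
                                    asymptote = tgt - sign(tgt) * te_planted,
                                    seed = seeds[s, 1 + ci]))
    tes <- numeric(length(blk$trials))
    for (k in seq_along(blk$trials)) {
      out <- analyze_lift_trial(blk$trials[[k]], cfg)
      tes[k] <- out$te
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sid, condition = cond, trial = k,
        lift_onset_s = (out$lift_onset_index - 1) / 1000,
        tcom_nmm = out$tcom_at_onset, te_nmm = out$te,
        target_nmm = out$target_torque)
    }
    te_by_cond[cond] <- condition_te(tes, cfg$condition_last_n,
                                     cfg$trials_per_block)$mean_te
  }
  subj[[s]] <- data.frame(subject = sid, r_te = te_by_cond[["right"]],
                          l_te = te_by_cond[["left"]],
                          c_te = te_by_cond[["center"]])
}
trials <- do.call(rbind, rows)
subjects <- do.call(rbind, subj)
write.csv(trials, "results/torque_outcomes.csv", row.names = FALSE)
write.csv(subjects, "results/subject_te.csv", row.names = FALSE)

first5 <- with(trials, tapply(te_nmm[trial <= 5], condition[trial <= 5], mean))
last5 <- with(trials, tapply(te_nmm[trial > 5], condition[trial > 5], mean))
cat(sprintf("Analyzed %d lifts for %d subjects.\n", nrow(trials), nrow(subjects)))
cat("Mean TE (N mm), trials 1-5 vs 6-10 — anticipatory learning within blocks:\n")
print(round(rbind(first_half = first5, second_half = last5), 1))
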