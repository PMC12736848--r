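#!/usr/bin/env Rscript
# Stage 1 — simulate the study's inputs.
#
# Generates the synthetic 39-subject cohort with its planted effect structure
# (higher right-condition torque error -> higher total force; female gender,
# older age and stronger pinch -> lower), writes the planted table, and emits
# one subject's raw files in the pipeline's text dialects as format examples.
# Later stages regenerate each subject's raw signals deterministically from
# the same master seed, so no bulk raw-data store is needed.

suppressPackageStartupMessages(library(beadmaze))
seed <- 1L
dir.create("results/example_raw", recursive = TRUE, showWarnings = FALSE)

gc <- gen_cohort(cohort_spec(n = 39, seed = seed))
write_cohort(gc$cohort, "results/planted_cohort.csv")

cat(sprintf("Simulated cohort: %d subjects (%d aged 5-10, %d aged 15-17; %d girls)\n",
            nrow(gc$cohort), sum(gc$cohort$age <= 10), sum(gc$cohort$age >= 15),
            sum(gc$cohort$gender == 1)))
cat("Planted per-SD effects on total force:\n")
print(gc$meta$beta[gc$meta$beta != 0])

# format examples: one BMHFT trace and one lift trial for subject S01
tr <- gen_bmhft_trace(trace_spec(amplitude = 0.8, seed = study_seeds(39, seed)[1, 1] + 1),
                      subject_id = "S01", trial_id = 1L)
write_trace(tr$trace, "results/example_raw/S01_bmhft_trial1.csv")
blk <- gen_lift_block(lift_spec(condition = "right",
                                seed = study_seeds(39, seed)[1, 2]))
write_lift_trial(blk$trials[[1]],
                 "results/example_raw/S01_right_trial1_wrench.csv",
                 "results/example_raw/S01_right_trial1_position.csv")
write_lift_metadata(data.frame(subject = "S01", condition = "right", block = 1L,
                               trial = 1L,
                               wrench_file = "S01_right_trial1_wrench.csv",
                               position_file = "S01_right_trial1_position.csv"),
                    "results/example_raw/lift_trials.csv")
cat("Wrote results/planted_cohort.csv and example raw files under results/example_raw/\n")
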