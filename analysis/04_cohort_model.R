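#!/usr/bin/env Rscript
# Stage 4 — predictive model of BMHFT total force.
#
# Assembles the measured cohort (demographics and hand measures from the
# cohort table; torque errors and total force from the signal-level stages),
# then fits the standardized ridge regression with 5-fold cross-validated
# penalty on a 75/25 gender-stratified split, and reports train/test R2,
# AIC/BIC, the mean-|SHAP| feature ranking and the Bonferroni-corrected
# Spearman screen.

suppressPackageStartupMessages(library(beadmaze))
seed <- 1L
cfg <- default_config()

planted <- read_cohort("results/planted_cohort.csv")
scores <- read.csv("results/bmhft_subject_scores.csv")
te <- read.csv("results/subject_te.csv")

cohort <- planted
stopifnot(identical(cohort$subject_id, scores$subject),
          identical(cohort$subject_id, te$subject))
cohort$total_force <- scores$mean_total_force
cohort$r_te <- te$r_te
cohort$l_te <- te$l_te
write_cohort(cohort, "results/cohort.csv")

report <- run_cohort_model(cohort, cfg, seed = seed)
write_model_report(report, "results/model_report.json")
ranking <- data.frame(feature = report$ranking,
                      mean_abs_shap = unname(report$mean_abs_shap))
write.csv(ranking, "results/shap_ranking.csv", row.names = FALSE)
write.csv(report$spearman, "results/spearman_screen.csv", row.names = FALSE)

cat(sprintf("Ridge model on %d train / %d test subjects (lambda = %.3g):\n",
            report$n_train, report$n_test, report$lambda))
cat(sprintf("  R2 train = %.2f, R2 test = %.2f, AIC = %.2f, BIC = %.2f\n",
            report$r2_train, report$r2_test, report$aic, report$bic))
cat("Features ranked by mean |SHAP| (top 4):\n")
print(head(ranking, 4))
cat("Significant Spearman correlations after Bonferroni (alpha = 0.05):\n")
print(subset(report$spearman, significant,
             select = c(feature, rho, p_adj)))
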