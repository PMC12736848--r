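# beadmaze

Analysis pipeline for force-sensor-based assessment of hand function in
children, for researchers and clinician-scientists working with instrumented
dexterity tests.

Two tasks feed one predictive model:

* **Bead Maze Hand Function Test (BMHFT).** Triaxial wire forces (1000 Hz)
  are zero-phase low-pass filtered (30 Hz, 5th-order Butterworth), trials
  are segmented — start at the first sustained (≥ 10 ms) exit of any channel
  from its baseline band mean ± 2 SD, end at the first y-force drop to
  −0.2 N — and scored by the L1-norm total force
  `Σ (|fx| + |fy| + |fz|)` from contact to end, averaged over 5 trials.
  Lower total force = finer force control.
* **Dexterous manipulation task.** A grip device with a hidden off-center
  mass creates a ±122 N·mm frontal-plane torque. Lift onset is detected from
  vertical position (mean + 2 SD sustained 200 ms, position resampled to the
  force rate); compensatory torque at onset,
  `Tcom = F̄n·(y_th − y_fi) + (w/2)·(Ft_th − Ft_fi)`,
  is compared with the target to give the torque error `TE = |Tcom − T_target|`,
  averaged over the last 5 trials per condition — a measure of anticipatory
  (feedforward) control.
* **Cohort model.** A standardized ridge regression
  (`min ‖y − β₀ − Xβ‖² + λ‖β‖²`, 5-fold cross-validated λ, 75/25
  gender-stratified split) predicts total force from nine features (age,
  gender, hand span/length, pinch/key strength, stereognosis, right/left
  TE), with exact linear SHAP attributions ranked by mean |SHAP| and a
  Bonferroni-corrected Spearman screen of features against predictions.

Seeded generators synthesize all raw inputs with planted ground truth —
detectable contact/end events, torque-learning trajectories converging to
±122 N·mm, and a correlated 9-feature cohort with a known effect vector — so
the full chain is testable end to end without any data download.

## Worked example

```r
library(beadmaze)

# one synthetic BMHFT trial, segmented and scored from the noisy signal
g   <- gen_bmhft_trace(trace_spec(start_time_s = 1.5, end_time_s = 4.2, seed = 7))
res <- score_bmhft_trial(g$trace)
```

```
trial start 1.504 s, end 4.200 s, duration 2.696 s
total force 3361.8 (N per sample), integral 3.36 N s
```

The planted contact at 1.5 s is found at 1.504 s (the force rise takes a few
milliseconds to clear the 2 SD band) and the planted −0.2 N end event at
4.2 s is found on the sample. The score is the L1 sum over that segment, in
raw per-sample units with the rate-normalized N·s integral alongside.

```r
# a 10-trial lift block: torque converges toward the +122 N mm target
blk <- gen_lift_block(lift_spec(condition = "right", seed = 3))
out <- analyze_lift_trial(blk$trials[[10]])
```

```
trial 10: onset 1.201 s, Tcom 132.1 N mm, TE 10.1 N mm
```

By trial 10 the planted learner applies 132 N·mm against the 122 N·mm
target, leaving a 10 N·mm torque error at the detected onset.

## The analysis

`analysis/` holds the numbered drivers of the full synthetic study
(n = 39, master seed 1); each writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # cohort + example raw files
Rscript analysis/02_bmhft_scores.R  # segment + score 195 BMHFT trials
Rscript analysis/03_torque_error.R  # 1170 lifts -> per-condition TE
Rscript analysis/04_cohort_model.R  # ridge + SHAP + Spearman report
```

The final stage prints, for seed 1:

```
Ridge model on 29 train / 10 test subjects (lambda = 3.16):
  R2 train = 0.77, R2 test = -0.02, AIC = 266.30, BIC = 281.34
Features ranked by mean |SHAP| (top 4):
         feature mean_abs_shap
1           r_te      58.23490
2      hand_span      47.41475
3         gender      46.57718
4 pinch_strength      24.06245
```

Right-condition torque error dominates the ranking, and the Spearman screen
recovers the planted directions (higher TE → higher total force; female
gender, older age, stronger pinch → lower). Test-set R² on 10 subjects is
extremely noisy and swings seed to seed; see the methods vignette
(`vignettes/beadmaze-methods.Rmd`) for model details, defaults and
limitations. `run_report()` runs the same chain in one call and is
byte-reproducible for a fixed seed.

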