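mk_lift <- function(tcom, n = 2600, rate = 1000, onset_s = 1.2, width = 50,
                    f0 = 10, load = 4.14, pos_noise = 0) {
  t <- (seq_len(n) - 1) / rate
  ramp <- pmin(pmax((t - 0.3) / 0.3, 0), 1)
  d_tan <- tcom / (width / 2)
  th <- digit_wrench(f0 * ramp, (load / 2 + d_tan / 2) * ramp, rep(0, n), rate)
  fi <- digit_wrench(f0 * ramp, (load / 2 - d_tan / 2) * ramp, rep(0, n), rate)
  np <- round(n / rate * 120)
  tp <- (seq_len(np) - 1) / 120
  u <- pmin(pmax(tp - onset_s, 0), 1)
  pos <- uniform_series(100 * sin(pi * u / 2) + rnorm(np, 0, pos_noise), 120)
  lift_trial(th, fi, pos, "right", width)
}

test_that("lift onset matches the planted rise and the scan oracle", {
  expect_error(find_lift_onset(uniform_series(rnorm(360, 0, 0.01), 120)),
               class = "beadmaze_no_lift")

  tr <- mk_lift(100, pos_noise = 1e-4)
  onset <- find_lift_onset(tr$position_z, 1000)
  expect_gte(as.integer(onset), 1200L)
  expect_lte(as.integer(onset), 1205L)  # within 5 ms of the 1.2 s rise
  pos_rs <- attr(onset, "resampled")
  bs <- baseline_stats(pos_rs, c(1, 200))
  expect_identical(as.integer(onset),
                   scan_crossing_oracle(pos_rs$values, bs$mean + 2 * bs$sd,
                                        "above", 200L))

  # a ~150 ms bump before the real lift is rejected by the 200 ms rule
  np <- 360
  tp <- (seq_len(np) - 1) / 120
  bump <- 5 * exp(-((tp - 0.8) / 0.022)^2)
  bump[abs(tp - 0.8) > 0.075] <- 0                 # above-noise span: 150 ms
  u <- pmin(pmax(tp - 1.6, 0), 1)
  pos <- uniform_series(bump + 100 * sin(pi * u / 2) + rnorm(np, 0, 1e-4), 120)
  onset2 <- find_lift_onset(pos, 1000)
  expect_gte(as.integer(onset2), 1550L)
  pos_rs2 <- attr(onset2, "resampled")
  bs2 <- baseline_stats(pos_rs2, c(1, 200))
  expect_identical(as.integer(onset2),
                   scan_crossing_oracle(pos_rs2$values, bs2$mean + 2 * bs2$sd,
                                        "above", 200L))
})

test_that("compensatory torque follows two-surface grip statics", {
  n <- 1000
  sym <- lift_trial(digit_wrench(rep(10, n), rep(2, n), rep(3, n)),
                    digit_wrench(rep(10, n), rep(2, n), rep(3, n)),
                    uniform_series(rep(0, 241), 120), "center", 50)
  expect_equal(compensatory_torque(sym, 500L), 0)

  # 10 N mean normal force, 6 mm CoP difference, 2.48 N tangential difference,
  # 50 mm width: 10*6 + 25*2.48 = 122 N mm
  tr <- lift_trial(digit_wrench(rep(10, n), rep(3.24, n), rep(3, n)),
                   digit_wrench(rep(10, n), rep(0.76, n), rep(-3, n)),
                   uniform_series(rep(0, 241), 120), "right", 50)
  expect_equal(compensatory_torque(tr, 500L), 122)

  # adding the same constant to both tangential forces changes nothing
  tr2 <- lift_trial(digit_wrench(rep(10, n), rep(3.24 + 5, n), rep(3, n)),
                    digit_wrench(rep(10, n), rep(0.76 + 5, n), rep(-3, n)),
                    uniform_series(rep(0, 241), 120), "right", 50)
  expect_equal(compensatory_torque(tr2, 500L), 122)

  # linear in each wrench component separately
  base <- compensatory_torque(tr, 500L)
  tr3 <- tr; tr3$thumb$cop_y$values <- 2 * tr$thumb$cop_y$values
  d_cop <- compensatory_torque(tr3, 500L) - base
  tr4 <- tr; tr4$thumb$cop_y$values <- 3 * tr$thumb$cop_y$values
  expect_equal(compensatory_torque(tr4, 500L) - base, 2 * d_cop)

  weak <- lift_trial(digit_wrench(rep(0.05, n), rep(0, n), rep(0, n)),
                     digit_wrench(rep(0.05, n), rep(0, n), rep(0, n)),
                     uniform_series(rep(0, 241), 120), "center", 50)
  expect_error(compensatory_torque(weak, 500L),
               class = "beadmaze_unreliable_contact")
})

test_that("torque error identities and sign conventions hold", {
  expect_identical(torque_error(122, "right"), 0)
  expect_identical(torque_error(0, "right"), 122)
  expect_identical(torque_error(-50, "left"), 72)
  expect_identical(torque_error(0, "center"), 0)
  expect_identical(target_torque("left"), -122)
  # invariant under simultaneous sign flip of torque and target side
  for (tc in c(-80, 0, 35, 140))
    expect_equal(torque_error(tc, "right"), torque_error(-tc, "left"))
})

test_that("condition TE averages the last five trials of a block", {
  expect_equal(condition_te(c(50, 40, 30, 20, 10, 8, 6, 5, 4, 2))$mean_te, 5)
  expect_equal(condition_te(rep(0, 10))$mean_te, 0)
  expect_error(condition_te(c(1, 2, 3)), class = "beadmaze_too_few_trials")
  out <- condition_te(1:7)
  expect_equal(out$mean_te, mean(3:7))
  expect_equal(out$qc_flags, "unexpected_block_length")
})

test_that("planted torque trajectories are recovered exactly at planted onsets", {
  blk <- gen_lift_block(lift_spec(condition = "right", seed = 21))
  for (k in seq_along(blk$trials)) {
    out <- analyze_lift_trial(blk$trials[[k]])
    expect_lte(abs(out$lift_onset_index - blk$planted$onset_index[k]), 2L)
    tcom_planted <- compensatory_torque(blk$trials[[k]],
                                        blk$planted$onset_index[k])
    expect_equal(tcom_planted, blk$planted$tcom[k], tolerance = 1e-9)
    expect_equal(abs(blk$planted$tcom[k] - 122), blk$planted$te[k],
                 tolerance = 1e-12)
    # pipeline TE agrees with the planted trajectory up to filter round-off
    expect_equal(out$te, blk$planted$te[k], tolerance = 1e-6)
  }
})

test_that("faster learning gives smaller end-of-block torque error", {
  mean_te_at <- function(r, seed) {
    blk <- gen_lift_block(lift_spec(learning_rate = r, noise_sd = 0, seed = seed))
    condition_te(blk$planted$te)$mean_te
  }
  for (sd_i in 1:20) {
    tes <- vapply(c(0.2, 0.45, 0.7, 0.95), mean_te_at, numeric(1), seed = sd_i)
    expect_true(all(diff(tes) < 0))
  }
})

test_that("cop conversion from a raw wrench flags unreliable contact", {
  fn <- uniform_series(c(0.05, 1, 2, 4), 1000)
  mx <- uniform_series(c(1, 2, 6, 8), 1000)
  cop <- wrench_to_cop(mx, fn)
  expect_true(is.na(cop$values[1]))
  expect_equal(cop$values[2:4], c(2, 3, 2))
})
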