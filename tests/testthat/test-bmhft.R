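test_that("DC offset removal zeroes the baseline mean exactly", {
  n <- 1000
  tr <- mk_trace(rep(0.5, n), rep(-0.31, n), rep(0, n))
  out <- remove_dc_offset(tr, c(1, 200))
  for (ch in c("fx", "fy", "fz"))
    expect_equal(mean(out[[ch]]$values[1:200]), 0)
  # signal region is shifted by exactly the baseline mean (subtraction oracle)
  sig <- c(rep(0.31, 300), 0.31 + sin(seq(0, 3, length.out = 700)))
  tr2 <- mk_trace(sig, sig, sig)
  out2 <- remove_dc_offset(tr2, c(1, 300))
  expect_equal(out2$fx$values, sig - 0.31)
})

test_that("trial start detection finds the earliest sustained band exit", {
  set.seed(3)
  n <- 4000
  quiet <- function() rnorm(n, 0, 0.01)
  # all-noise trace stays inside the band
  tr0 <- mk_trace(quiet(), quiet(), quiet())
  bl0 <- trace_baseline(tr0, c(1, 200))
  expect_error(find_trial_start(tr0, bl0), class = "beadmaze_no_trial")

  # a clean step on fz is found at its first sample
  fz <- rep(0, n); fz[2500:n] <- 1
  tr1 <- mk_trace(rep(0, n), rep(0, n), fz)
  bl <- lapply(c(fx = 1, fy = 1, fz = 1), function(i)
    list(mean = 0, sd = 0.01, window = c(1L, 200L)))
  got <- find_trial_start(tr1, bl)
  expect_equal(as.integer(got), 2500L)
  expect_equal(attr(got, "channel"), "fz")

  # a 5 ms fx spike is ignored; the sustained fy rise at 1800 wins
  fx <- rep(0, n); fx[1000:1004] <- 1
  fy <- rep(0, n); fy[1800:n] <- 0.5
  tr2 <- mk_trace(fx, fy, rep(0, n))
  got2 <- find_trial_start(tr2, bl)
  expect_equal(as.integer(got2), 1800L)
  # agrees with the exhaustive scan oracle channel by channel
  expect_identical(scan_crossing_oracle(abs(fy), 0.02, "above", 10L), 1800L)
  expect_identical(scan_crossing_oracle(abs(fx), 0.02, "above", 10L), NA_integer_)

  # the band is two-sided: a negative-going sustained pull is also a start
  fyneg <- rep(0, n); fyneg[2100:n] <- -0.5
  tr3 <- mk_trace(rep(0, n), fyneg, rep(0, n))
  expect_equal(as.integer(find_trial_start(tr3, bl)), 2100L)
})

test_that("trial end is the first y-force sample at or below -0.2 N", {
  n <- 8000
  fy <- rep(0.3, n)
  fy[6000:6200] <- -0.25
  fy[7000:7200] <- -0.30
  tr <- mk_trace(rep(0, n), fy, rep(0, n))
  expect_equal(find_trial_end(tr, 100L), 6000L)

  fy2 <- rep(0.3, n); fy2[6000:6500] <- -0.15
  tr2 <- mk_trace(rep(0, n), fy2, rep(0, n))
  expect_error(find_trial_end(tr2, 100L), class = "beadmaze_no_end")

  # exact threshold sample counts (<=, not <)
  fy3 <- rep(0.3, n); fy3[5000] <- -0.2
  tr3 <- mk_trace(rep(0, n), fy3, rep(0, n))
  expect_equal(find_trial_end(tr3, 100L), 5000L)
})

test_that("L1 total force matches direct re-summation and its invariances", {
  n <- 500
  tr <- mk_trace(rep(1, n), rep(-2, n), rep(0, n))
  seg <- trial_segment(1L, 100L, 1000)  # inclusive window of 100 samples
  sc <- total_force_l1(tr, seg)
  expect_identical(sc$total_force, 300)
  expect_equal(sc$total_force_integral, 300 / 1000)

  z <- mk_trace(rep(0, n), rep(0, n), rep(0, n))
  expect_identical(total_force_l1(z, seg)$total_force, 0)

  set.seed(9)
  fx <- rnorm(n); fy <- rnorm(n); fz <- rnorm(n)
  trr <- mk_trace(fx, fy, fz)
  seg2 <- trial_segment(37L, 421L, 1000)
  w <- 37:421
  oracle <- sum(abs(fx[w])) + sum(abs(fy[w])) + sum(abs(fz[w]))
  expect_equal(total_force_l1(trr, seg2)$total_force, oracle, tolerance = 1e-9)

  # invariant to sign flips of any channel
  flip <- mk_trace(-fx, fy, -fz)
  expect_equal(total_force_l1(flip, seg2)$total_force,
               total_force_l1(trr, seg2)$total_force)

  # scaling all forces by c > 0 scales the score by exactly c
  sc3 <- mk_trace(3 * fx, 3 * fy, 3 * fz)
  expect_equal(total_force_l1(sc3, seg2)$total_force,
               3 * total_force_l1(trr, seg2)$total_force)

  # monotone non-decreasing in segment length
  tf_len <- vapply(seq(100, 450, by = 50), function(e)
    total_force_l1(trr, trial_segment(37L, e, 1000))$total_force, numeric(1))
  expect_true(all(diff(tf_len) >= 0))

  expect_error(total_force_l1(trr, list(start_index = 10L, end_index = 10L,
                                        duration_s = 0)),
               class = "beadmaze_invalid_segment")
})

test_that("subject score averages trials and guards the protocol", {
  mk_score <- function(tf, rate = 1000) {
    structure(list(total_force = tf, total_force_integral = tf / rate,
                   duration_s = 1, rate = rate, qc_flags = character()),
              class = "bmhft_score")
  }
  expect_equal(score_subject(lapply(c(100, 100, 100, 100, 100), mk_score))$mean_total_force,
               100)
  expect_warning(out <- score_subject(lapply(1:5, mk_score), expected_trials = 4L),
                 "4 were expected")
  expect_equal(out$mean_total_force, 3)
  expect_equal(out$qc_flags, "unexpected_trial_count")
  expect_error(score_subject(list()), class = "beadmaze_no_trials")
  expect_error(score_subject(list(mk_score(1, 1000), mk_score(2, 500))),
               class = "beadmaze_rate_mismatch")
})

test_that("planted BMHFT events are recovered from noisy traces", {
  for (sd_i in 1:20) {
    g <- gen_bmhft_trace(trace_spec(seed = 100 + sd_i))
    res <- score_bmhft_trial(g$trace)
    expect_length(res$qc_flags, 0)
    expect_lte(abs(res$segment$start_index - g$truth$start_index), 2L)
    expect_lte(abs(res$segment$end_index - g$truth$end_index), 2L)
  }
})

test_that("the full trial scorer flags undetectable traces instead of failing", {
  set.seed(5)
  n <- 3000
  noise <- function() rnorm(n, 0, 0.01)
  res <- score_bmhft_trial(mk_trace(noise(), noise(), noise()))
  expect_null(res$score)
  expect_true("no_trial_detected" %in% res$qc_flags)

  # detectable start but fy never drops: flagged as missing end
  fz <- c(rep(0, 1500), rep(1, n - 1500)) + noise()
  res2 <- score_bmhft_trial(mk_trace(noise(), noise(), fz))
  expect_true("no_end_detected" %in% res2$qc_flags)
})
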