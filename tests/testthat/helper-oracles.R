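# Independent oracles used to verify the pipeline's operations. These are
# deliberately naive (exhaustive scans, DFT sums, full Shapley enumeration,
# generic numeric minimization) and share no code with the implementation.

# exhaustive window scan: first index whose m-sample window satisfies the
# direction strictly at every sample
scan_crossing_oracle <- function(values, threshold, direction, m) {
  n <- length(values)
  if (m > n) return(NA_integer_)
  sat <- if (direction == "above") values > threshold else values < threshold
  for (i in seq_len(n - m + 1L)) {
    if (all(sat[i:(i + m - 1L)])) return(i)
  }
  NA_integer_
}

# band power from a plain DFT; Hann-windowed so passband leakage from the
# non-periodic segment does not mask stopband attenuation
dft_band_power <- function(x, rate, f_lo, f_hi) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  X <- stats::fft(x * w)
  freq <- (seq_len(n) - 1) * rate / n
  keep <- freq >= f_lo & freq <= min(f_hi, rate / 2)
  sum(Mod(X[keep])^2) / n
}

# exact Shapley values of a linear model under the mean-imputation value
# function, by enumeration over all coalitions
brute_shapley_linear <- function(beta0, beta, x, means) {
  p <- length(beta)
  vfun <- function(mask) beta0 + sum(beta * ifelse(mask, x, means))
  phi <- numeric(p)
  for (j in seq_len(p)) {
    others <- setdiff(seq_len(p), j)
    for (k in 0:(p - 1L)) {
      w <- factorial(k) * factorial(p - k - 1L) / factorial(p)
      subsets <- if (k == 0L) list(integer(0)) else
        asplit(utils::combn(others, k), 2)
      for (S in subsets) {
        mask <- logical(p)
        mask[unlist(S)] <- TRUE
        with_j <- mask; with_j[j] <- TRUE
        phi[j] <- phi[j] + w * (vfun(with_j) - vfun(mask))
      }
    }
  }
  phi
}

# penalized least squares by generic numeric minimization (BFGS on the exact
# gradient-free objective)
brute_ridge <- function(X, y, lambda) {
  X <- as.matrix(X)
  obj <- function(par) {
    sum((y - par[1] - X %*% par[-1])^2) + lambda * sum(par[-1]^2)
  }
  fit <- stats::optim(rep(0, ncol(X) + 1L), obj, method = "BFGS",
                      control = list(maxit = 50000, reltol = 1e-16))
  list(intercept = fit$par[1], coefficients = fit$par[-1])
}

# quick constructor for a trace with given channel vectors at 1000 Hz
mk_trace <- function(fx, fy, fz, rate = 1000) {
  beadmaze::force_trace(fx, fy, fz, rate = rate, subject_id = "T", trial_id = 1L)
}
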