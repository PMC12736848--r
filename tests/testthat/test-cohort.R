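toy_xy <- function(n = 40, p = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  b <- rep_len(c(1.5, -0.7, 0.2), p)
  y <- drop(2 + X %*% b + rnorm(n, 0, 0.5))
  list(X = X, y = y)
}

test_that("standardization is population z-scoring with reusable parameters", {
  df <- data.frame(a = c(1, 2, 3), b = c(0, 10, 20))
  std <- standardize_features(df, c("a", "b"))
  expect_equal(std$data$a, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(round(std$data$a[1], 4), -1.2247)
  # already-standardized input is unchanged
  again <- standardize_features(std$data, c("a", "b"))
  expect_equal(again$data$a, std$data$a, tolerance = 1e-12)
  # test rows are transformed with training parameters, not their own
  test_df <- apply_standardization(data.frame(a = 2, b = 30), std$center, std$scale)
  expect_equal(test_df$a, 0)
  expect_equal(test_df$b, 20 / std$scale[["b"]])

  expect_error(standardize_features(data.frame(a = rep(4, 5)), "a"),
               class = "beadmaze_constant_feature")
  expect_error(standardize_features(data.frame(a = c(1, NA, 3)), "a"),
               class = "beadmaze_missing_values")
})

test_that("stratified split reproduces protocol sizes and determinism", {
  df <- data.frame(gender = rep(c(0, 1), length.out = 39), y = rnorm(39))
  sp <- split_train_test(df, seed = 4)
  expect_equal(nrow(sp$train), 29)
  expect_equal(nrow(sp$test), 10)
  expect_equal(nrow(sp$train) + nrow(sp$test), 39)
  # proportions preserved within rounding
  expect_lte(abs(mean(sp$test$gender) - mean(df$gender)), 0.15)

  df8 <- data.frame(gender = rep(c(0, 1), each = 4), y = rnorm(8))
  sp8 <- split_train_test(df8, seed = 1)
  expect_equal(sum(sp8$test$gender == 0), 1)
  expect_equal(sum(sp8$test$gender == 1), 1)
  expect_equal(nrow(sp8$train), 6)

  sp_a <- split_train_test(df, seed = 99)
  sp_b <- split_train_test(df, seed = 99)
  expect_identical(sp_a$test, sp_b$test)

  expect_error(split_train_test(data.frame(gender = c(0, rep(1, 9)), y = rnorm(10))),
               class = "beadmaze_stratum_too_small")
})

test_that("closed-form ridge matches OLS at zero penalty and shrinks to the mean", {
  d <- toy_xy()
  fit0 <- ridge_closed_form(d$X, d$y, 0)
  ols <- lm(d$y ~ d$X)
  expect_equal(unname(fit0$coefficients), unname(coef(ols)[-1]), tolerance = 1e-10)
  expect_equal(fit0$intercept, unname(coef(ols)[1]), tolerance = 1e-10)

  fit_inf <- ridge_closed_form(d$X, d$y, 1e9)
  expect_lt(max(abs(fit_inf$coefficients)), 1e-6)
  expect_equal(fit_inf$intercept, mean(d$y), tolerance = 1e-6)

  Xc <- cbind(d$X[, 1], d$X[, 1])
  expect_error(ridge_closed_form(Xc, d$y, 0), class = "beadmaze_singular_system")
})

test_that("duplicated predictors share the coefficient 1/k-fold", {
  set.seed(2)
  x <- rnorm(50)
  y <- 3 * x + rnorm(50, 0, 0.3)
  lam <- 4
  for (k in 2:3) {
    Xk <- matrix(rep(x, k), ncol = k)
    fit_k <- ridge_closed_form(Xk, y, lam)
    # each duplicate equals 1/k of what the single predictor gets under the
    # equivalent penalty lam / k
    fit_1 <- ridge_closed_form(matrix(x), y, lam / k)
    expect_equal(unname(fit_k$coefficients),
                 rep(fit_1$coefficients[[1]] / k, k), tolerance = 1e-8)
    # and agrees with generic numeric minimization of the penalized objective
    bf <- brute_ridge(Xk, y, lam)
    expect_equal(unname(fit_k$coefficients), bf$coefficients, tolerance = 1e-6)
  }
})

test_that("ridge coefficient norm is non-increasing along the penalty grid", {
  d <- toy_xy(60, 5, seed = 8)
  norms <- vapply(default_lambda_grid(), function(l)
    sqrt(sum(ridge_closed_form(d$X, d$y, l)$coefficients^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("closed-form ridge agrees with glmnet as an independent solver", {
  library(glmnet)
  d <- toy_xy(80, 4, seed = 5)
  n <- length(d$y)
  lam_mine <- 12
  # glmnet's gaussian objective is (1/2n) RSS + lambda/2 ||b||^2 on the
  # internally y-standardized problem, so its penalty corresponds to
  # lambda * sd_pop(y) / n in the unnormalized objective
  s <- lam_mine * sqrt(stats::var(d$y) * (n - 1) / n) / n
  g <- glmnet(d$X, d$y, alpha = 0, lambda = c(1, s, 0.001),
              standardize = FALSE, intercept = TRUE, thresh = 1e-16)
  mine <- ridge_closed_form(d$X, d$y, lam_mine)
  expect_equal(unname(as.numeric(coef(g, s = s, exact = TRUE,
                                      x = d$X, y = d$y))[-1]),
               unname(mine$coefficients), tolerance = 1e-6)
})

test_that("cross-validated penalty selection behaves sensibly", {
  d <- toy_xy(60, 4, seed = 3)
  single <- fit_ridge_cv(d$X, d$y, lambda_grid = 0.37, seed = 1)
  expect_equal(single$lambda, 0.37)

  # pure-noise outcome: the selected penalty sits at or near the grid top
  grid <- default_lambda_grid()
  top <- 0
  for (sd_i in 1:10) {
    set.seed(sd_i)
    Xn <- matrix(rnorm(40 * 5), 40, 5)
    yn <- rnorm(40)
    cvn <- fit_ridge_cv(Xn, yn, grid, seed = sd_i)
    if (cvn$lambda >= grid[20]) top <- top + 1
  }
  expect_gte(top, 6)

  # planted signal: finite selection, not pinned at the top
  cvs <- fit_ridge_cv(d$X, d$y, grid, seed = 2)
  expect_lt(cvs$lambda, grid[20])
  # determinism
  expect_identical(fit_ridge_cv(d$X, d$y, grid, seed = 7)$lambda,
                   fit_ridge_cv(d$X, d$y, grid, seed = 7)$lambda)
})

test_that("model scores match hand-computed R2, AIC and BIC", {
  d <- toy_xy()
  fit <- ridge_closed_form(d$X, d$y, 1)
  # perfect fit on its own predictions
  yhat <- predict_ridge(fit, d$X)
  perfect <- model_scores(fit, d$X, yhat)
  expect_equal(perfect$r2_train, 1)

  # intercept-only predictions give R2 = 0 on the fitting set
  fit0 <- ridge_closed_form(d$X, d$y, 1e12)
  expect_equal(model_scores(fit0, d$X, d$y)$r2_train, 0, tolerance = 1e-6)

  # 5-point toy against the Gaussian profile-likelihood formulas
  X5 <- matrix(c(-2, -1, 0, 1, 2), dimnames = list(NULL, "x"))
  y5 <- c(0.1, 0.9, 2.2, 2.8, 4.1)
  f5 <- ridge_closed_form(X5, y5, 0.5)
  ms <- model_scores(f5, X5, y5)
  rss <- sum((y5 - predict_ridge(f5, X5))^2)
  p <- 1 + 2
  expect_equal(ms$aic, 5 * log(rss / 5) + 2 * p)
  expect_equal(ms$bic, 5 * log(rss / 5) + p * log(5))

  expect_error(model_scores(f5, X5, rep(1, 5)), class = "beadmaze_zero_variance")
})

test_that("linear SHAP satisfies its axioms and matches brute-force Shapley", {
  d <- toy_xy(30, 3, seed = 6)
  fit <- ridge_closed_form(d$X, d$y, 2)
  sh <- shap_linear(fit, d$X)
  # subject exactly at the background means gets zero attribution
  at_means <- shap_linear(fit, rbind(colMeans(d$X)), colMeans(d$X))
  expect_lt(max(abs(at_means$shap)), 1e-12)
  # local accuracy for every subject
  pred <- predict_ridge(fit, d$X)
  expect_lt(max(abs(rowSums(sh$shap) + sh$base_value - pred)), 1e-10)
  # equals enumeration over all coalitions with mean imputation
  for (i in c(1, 17)) {
    bf <- brute_shapley_linear(fit$intercept, fit$coefficients, d$X[i, ],
                               colMeans(d$X))
    expect_equal(unname(sh$shap[i, ]), bf, tolerance = 1e-10)
  }
  # deterministic alphabetical tie-break
  fit_t <- structure(list(coefficients = c(b = 1, a = 1), intercept = 0),
                     class = "ridge_fit")
  Xt <- cbind(b = c(-1, 1), a = c(1, -1))
  sh_t <- shap_linear(fit_t, Xt, c(b = 0, a = 0))
  expect_equal(sh_t$ranking, c("a", "b"))
})

test_that("SHAP ranking is invariant to affine rescaling of raw features", {
  gc <- gen_cohort(cohort_spec(seed = 31))
  run1 <- run_cohort_model(gc$cohort, seed = 3)
  scaled <- gc$cohort
  scaled$pinch_strength <- scaled$pinch_strength * 9.81 + 2  # kg -> N offset
  scaled$hand_span <- scaled$hand_span * 10                  # cm -> mm
  run2 <- run_cohort_model(scaled, seed = 3)
  expect_identical(run1$ranking, run2$ranking)
  expect_equal(run1$mean_abs_shap, run2$mean_abs_shap, tolerance = 1e-8)
})

test_that("the split can stratify on outcome quartiles instead of gender", {
  gc <- gen_cohort(cohort_spec(seed = 44))
  cfg <- default_config()
  cfg$stratify_on <- "total_force_quartile"
  rep <- run_cohort_model(gc$cohort, cfg, seed = 2)
  expect_equal(c(rep$n_train, rep$n_test), c(29L, 10L))
  expect_length(rep$ranking, 9L)
})

test_that("Spearman screen matches the rank-formula oracle with Bonferroni", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5)
  y <- c(2, 1, 6, 1.2, 8, 2.2, 9)
  out <- spearman_screen(data.frame(x = x), y, m = 9)
  rho_oracle <- cor(rank(x), rank(y))
  expect_equal(out$rho, rho_oracle, tolerance = 1e-12)
  tstat <- rho_oracle * sqrt((7 - 2) / (1 - rho_oracle^2))
  p_oracle <- 2 * pt(abs(tstat), 7 - 2, lower.tail = FALSE)
  expect_equal(out$p_raw, p_oracle, tolerance = 1e-10)
  expect_equal(out$p_adj, min(1, 9 * p_oracle))

  mono <- spearman_screen(data.frame(x = 1:8), (1:8)^3, m = 1)
  expect_equal(mono$rho, 1)
  expect_equal(mono$p_adj, mono$p_raw)

  const <- spearman_screen(data.frame(x = 1:8, c = rep(2, 8)), rnorm(8))
  expect_true(is.na(const$rho[const$feature == "c"]))
})
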