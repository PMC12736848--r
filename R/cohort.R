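#' Names of the nine model features
#'
#' Feature set of the predictive model: demographics (age, gender coded
#' male = 0 / female = 1), hand size (span, length), strength (pinch, key),
#' stereognosis score (0-9), and torque errors from the right- and left-mass
#' manipulation conditions.
#'
#' @return Character vector of length 9.
#' @export
cohort_features <- function() {
  c("age", "gender", "hand_span", "hand_length", "pinch_strength",
    "key_strength", "stereognosis", "r_te", "l_te")
}

#' Z-score standardization (population-SD convention)
#'
#' Centers and scales feature columns to mean 0, SD 1 using the population
#' (divide-by-n) standard deviation. Parameters estimated from one table (the
#' training set) can be applied unchanged to another (the test set) via
#' [apply_standardization()].
#'
#' @param data data frame containing the feature columns.
#' @param features character vector of columns to standardize.
#' @return List: `data` (standardized copy), `center`, `scale` (named
#'   vectors). Errors name any constant or missing-valued feature.
#' @export
standardize_features <- function(data, features = cohort_features()) {
  stopifnot(is.data.frame(data), all(features %in% names(data)))
  center <- scale <- stats::setNames(numeric(length(features)), features)
  out <- data
  for (f in features) {
    x <- data[[f]]
    if (anyNA(x))
      stop_beadmaze(sprintf("feature '%s' contains missing values", f), "missing_values")
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))
    if (s == 0)
      stop_beadmaze(sprintf("feature '%s' is constant and cannot be standardized", f),
                    "constant_feature")
    center[f] <- m; scale[f] <- s
    out[[f]] <- (x - m) / s
  }
  list(data = out, center = center, scale = scale)
}

#' Apply previously estimated standardization parameters
#'
#' @param data data frame with the feature columns.
#' @param center,scale named vectors from [standardize_features()].
#' @return Data frame with the named columns transformed.
#' @export
apply_standardization <- function(data, center, scale) {
  for (f in names(center)) data[[f]] <- (data[[f]] - center[[f]]) / scale[[f]]
  data
}

#' Stratified train/test split
#'
#' Splits rows into disjoint, exhaustive train and test sets. The total test
#' size is `round(test_fraction * n)`; it is allocated across the strata of
#' `stratify_on` proportionally (largest-remainder rounding), so class
#' proportions are preserved within rounding. With n = 39 and the default
#' fraction this gives 29 training and 10 test rows. Deterministic given
#' `seed`.
#'
#' @param data data frame, n >= 8 rows.
#' @param test_fraction fraction held out (default 0.25).
#' @param stratify_on column name to stratify on (default `"gender"`, the one
#'   categorical feature).
#' @param seed integer seed for the within-stratum draws.
#' @return List with data frames `train` and `test`.
#' @export
split_train_test <- function(data, test_fraction = 0.25, stratify_on = "gender",
                             seed = 1L) {
  stopifnot(is.data.frame(data), stratify_on %in% names(data))
  n <- nrow(data)
  if (n < 8L) stop_beadmaze("need at least 8 rows to split", "too_few_rows")
  strata <- split(seq_len(n), data[[stratify_on]])
  sizes <- lengths(strata)
  if (any(sizes < 2L))
    stop_beadmaze("every stratum needs at least 2 rows", "stratum_too_small")
  n_test <- round(test_fraction * n)
  exact <- test_fraction * sizes
  base <- floor(exact)
  rem <- n_test - sum(base)
  if (rem > 0) {
    order_rem <- order(exact - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    order_rem <- order(exact - base)
    take <- order_rem[base[order_rem] > 0][seq_len(-rem)]
    base[take] <- base[take] - 1L
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  test_idx <- unlist(Map(function(idx, k) {
    if (k == 0L) integer() else sample(idx, k)
  }, strata, base), use.names = FALSE)
  list(train = data[setdiff(seq_len(n), test_idx), , drop = FALSE],
       test = data[sort(test_idx), , drop = FALSE])
}

# seed hygiene: set a local RNG state, restore the caller's afterwards
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Closed-form ridge regression with unpenalized intercept
#'
#' Minimizes `||y - b0 - X b||^2 + lambda * ||b||^2`. The intercept is left
#' out of the penalty: predictors and response are centered, the slope system
#' `(X'X + lambda I) b = X'y` is solved directly, and the intercept is
#' recovered as `mean(y) - colMeans(X) %*% b`.
#'
#' @param X numeric matrix (standardized features), n x p.
#' @param y numeric response vector.
#' @param lambda ridge penalty >= 0.
#' @return List of class `ridge_fit`: `coefficients` (named), `intercept`,
#'   `lambda`. Errors on a singular system at lambda = 0.
#' @export
ridge_closed_form <- function(X, y, lambda) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), lambda >= 0)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  A <- crossprod(Xc) + diag(lambda, ncol(X))
  if (lambda == 0 && qr(A)$rank < ncol(X))
    stop_beadmaze("X'X is singular at lambda = 0 (collinear predictors); use lambda > 0",
                  "singular_system")
  beta <- drop(solve(A, crossprod(Xc, y - ym)))
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, intercept = ym - drop(xm %*% beta),
                 lambda = lambda),
            class = "ridge_fit")
}

#' Predict from a ridge fit
#'
#' @param fit a `ridge_fit`.
#' @param X matrix or data frame with the fit's feature columns.
#' @return Numeric vector of predictions.
#' @export
predict_ridge <- function(fit, X) {
  X <- as.matrix(X)
  nm <- names(fit$coefficients)
  if (!is.null(nm) && !is.null(colnames(X))) {
    if (!all(nm %in% colnames(X)))
      stop_beadmaze("`X` lacks columns the model was fitted on", "feature_mismatch")
    X <- X[, nm, drop = FALSE]
  }
  if (ncol(X) != length(fit$coefficients))
    stop_beadmaze("`X` has the wrong number of columns for this fit",
                  "feature_mismatch")
  drop(fit$intercept + X %*% fit$coefficients)
}

#' Default log-spaced penalty grid
#'
#' @param from,to,length grid limits and size; default 1e-3 ... 1e3, 25 points.
#' @return Numeric vector, ascending.
#' @export
default_lambda_grid <- function(from = 1e-3, to = 1e3, length = 25L) {
  exp(seq(log(from), log(to), length.out = length))
}

#' Ridge penalty selection by K-fold cross-validation
#'
#' For each penalty on the grid, computes the mean out-of-fold R-squared over
#' a seeded K-fold partition (R-squared within each held-out fold, about that
#' fold's own mean), selects the penalty maximizing it (smallest such penalty
#' on ties), and refits on the full training data.
#'
#' @param X training feature matrix (standardized), y training response.
#' @param y numeric response.
#' @param lambda_grid candidate penalties (default [default_lambda_grid()]).
#' @param folds number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return List of class `ridge_cv`: `fit` (the refit `ridge_fit`), `lambda`,
#'   `cv_r2` (mean out-of-fold R-squared per grid point), `lambda_grid`,
#'   `folds`, `seed`.
#' @export
fit_ridge_cv <- function(X, y, lambda_grid = default_lambda_grid(), folds = 5L,
                         seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(lambda_grid) == 0L) stop_beadmaze("empty penalty grid", "invalid_grid")
  if (n < 2L * folds)
    stop_beadmaze("too few rows: every fold needs at least 2 samples", "too_few_rows")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  fold_id <- sample(rep_len(seq_len(folds), n))
  cv_r2 <- vapply(lambda_grid, function(lam) {
    mean(vapply(seq_len(folds), function(k) {
      hold <- fold_id == k
      fit <- ridge_closed_form(X[!hold, , drop = FALSE], y[!hold], lam)
      pred <- predict_ridge(fit, X[hold, , drop = FALSE])
      1 - sum((y[hold] - pred)^2) / sum((y[hold] - mean(y[hold]))^2)
    }, numeric(1)))
  }, numeric(1))
  best <- lambda_grid[which.max(cv_r2)]
  structure(list(fit = ridge_closed_form(X, y, best), lambda = best,
                 cv_r2 = cv_r2, lambda_grid = lambda_grid,
                 folds = folds, seed = seed),
            class = "ridge_cv")
}

#' Fit metrics: R-squared, AIC, BIC
#'
#' R-squared is `1 - RSS/TSS` on each set. AIC and BIC use the Gaussian
#' profile-likelihood form on the training set,
#' `n log(RSS/n) + 2 p` and `n log(RSS/n) + p log(n)`, with
#' `p = slopes + intercept + noise variance` free parameters. These values
#' are comparable across runs of this pipeline (the constant-free profile
#' form is used consistently), not across differently defined likelihoods.
#'
#' @param fit a `ridge_fit`.
#' @param X_train,y_train training set used for AIC/BIC and train R-squared.
#' @param X_test,y_test optional held-out set for test R-squared.
#' @return List: `r2_train`, `r2_test` (`NA` if no test set), `aic`, `bic`,
#'   `n_train`, `n_test`.
#' @export
model_scores <- function(fit, X_train, y_train, X_test = NULL, y_test = NULL) {
  r2 <- function(y, pred) {
    tss <- sum((y - mean(y))^2)
    if (tss == 0) stop_beadmaze("response has zero variance", "zero_variance")
    1 - sum((y - pred)^2) / tss
  }
  pred_tr <- predict_ridge(fit, X_train)
  rss <- sum((y_train - pred_tr)^2)
  n <- length(y_train)
  p <- length(fit$coefficients) + 2L  # slopes + intercept + noise variance
  list(r2_train = r2(y_train, pred_tr),
       r2_test = if (is.null(X_test)) NA_real_ else r2(y_test, predict_ridge(fit, X_test)),
       aic = n * log(rss / n) + 2 * p,
       bic = n * log(rss / n) + p * log(n),
       n_train = n,
       n_test = if (is.null(X_test)) 0L else length(y_test))
}

#' Exact SHAP values for a linear model
#'
#' For a linear model under the feature-independence (interventional)
#' background, the Shapley attribution of feature `j` to subject `i` has the
#' closed form `phi_ij = b_j (x_ij - m_j)` with `m_j` the background mean;
#' the base value is the prediction at the background means, and attributions
#' satisfy local accuracy `base + sum_j phi_ij = prediction_i` exactly.
#' Features are ranked by the mean absolute attribution, descending, with
#' ties broken alphabetically for determinism.
#'
#' @param fit a `ridge_fit`.
#' @param X matrix or data frame of feature values to explain.
#' @param background_means named vector of background means (default =
#'   column means of `X`).
#' @return List: `shap` (n x p matrix), `base_value`, `mean_abs_shap` (named,
#'   in ranking order), `ranking` (character).
#' @export
shap_linear <- function(fit, X, background_means = NULL) {
  X <- as.matrix(X[, names(fit$coefficients), drop = FALSE])
  if (is.null(background_means)) background_means <- colMeans(X)
  background_means <- background_means[names(fit$coefficients)]
  if (anyNA(background_means))
    stop_beadmaze("background means do not cover the model's features",
                  "background_mismatch")
  phi <- sweep(X, 2, background_means) %*% diag(fit$coefficients, ncol(X))
  colnames(phi) <- names(fit$coefficients)
  mabs <- colMeans(abs(phi))
  ord <- order(-mabs, names(mabs))
  list(shap = phi,
       base_value = fit$intercept + drop(background_means %*% fit$coefficients),
       mean_abs_shap = mabs[ord],
       ranking = names(mabs)[ord])
}

#' Spearman screen with Bonferroni correction
#'
#' Spearman rank correlation (average ranks) between each feature and the
#' model's predicted scores, with p-values from the large-sample t
#' approximation and Bonferroni adjustment `p_adj = min(1, m p)`. Constant
#' features have undefined correlation; they are flagged and reported as
#' `NA`.
#'
#' @param features data frame of raw (unstandardized) feature columns.
#' @param predicted numeric vector of model predictions, one per row.
#' @param m number of comparisons for the Bonferroni factor (default = number
#'   of features screened).
#' @param alpha significance level applied to adjusted p-values (default
#'   0.05).
#' @return Data frame: `feature`, `rho`, `p_raw`, `p_adj`, `significant`.
#' @export
spearman_screen <- function(features, predicted, m = ncol(features), alpha = 0.05) {
  stopifnot(is.data.frame(features), nrow(features) == length(predicted))
  if (nrow(features) < 4L)
    stop_beadmaze("need at least 4 observations for the Spearman screen", "too_few_rows")
  rows <- lapply(names(features), function(f) {
    x <- features[[f]]
    if (length(unique(x)) == 1L || length(unique(predicted)) == 1L)
      return(data.frame(feature = f, rho = NA_real_, p_raw = NA_real_,
                        p_adj = NA_real_, significant = NA))
    ct <- suppressWarnings(
      stats::cor.test(x, predicted, method = "spearman", exact = FALSE))
    p_adj <- min(1, m * ct$p.value)
    data.frame(feature = f, rho = unname(ct$estimate), p_raw = ct$p.value,
               p_adj = p_adj, significant = p_adj < alpha)
  })
  do.call(rbind, rows)
}

#' Full cohort modelling stage
#'
#' The statistical stage of the pipeline on a per-subject cohort table:
#' stratified 75/25 train/test split, z-scoring with training-set parameters,
#' 5-fold cross-validated ridge penalty selection, train/test R-squared and
#' AIC/BIC, exact linear SHAP attributions for all subjects (background =
#' training means), and a Bonferroni-corrected Spearman screen of the raw
#' features against the model's predictions on the full cohort.
#'
#' @param cohort data frame with the columns of [cohort_features()] plus
#'   `total_force`.
#' @param config list of settings, see [default_config()]. Setting
#'   `stratify_on = "total_force_quartile"` stratifies the split on outcome
#'   quartiles instead of a cohort column.
#' @param seed integer seed controlling the split and fold assignment.
#' @return List of class `model_report`; see fields in the implementation and
#'   the JSON written by [write_model_report()].
#' @export
run_cohort_model <- function(cohort, config = default_config(), seed = 1L) {
  feats <- cohort_features()
  stopifnot(all(c(feats, "total_force") %in% names(cohort)))
  seed <- as.integer(seed)
  if (identical(config$stratify_on, "total_force_quartile")) {
    q <- stats::quantile(cohort$total_force, c(0.25, 0.5, 0.75))
    cohort$total_force_quartile <- findInterval(cohort$total_force, q)
  }
  sp <- split_train_test(cohort, config$test_fraction, config$stratify_on, seed)
  std <- standardize_features(sp$train, feats)
  train_z <- std$data
  test_z <- apply_standardization(sp$test, std$center, std$scale)
  X_tr <- as.matrix(train_z[, feats]); y_tr <- train_z$total_force
  X_te <- as.matrix(test_z[, feats]);  y_te <- test_z$total_force
  cv <- fit_ridge_cv(X_tr, y_tr, config$lambda_grid, config$cv_folds, seed)
  scores <- model_scores(cv$fit, X_tr, y_tr, X_te, y_te)
  all_z <- apply_standardization(cohort, std$center, std$scale)
  X_all <- as.matrix(all_z[, feats])
  shap <- shap_linear(cv$fit, X_all, background_means = colMeans(X_tr))
  pred_all <- predict_ridge(cv$fit, X_all)
  spearman <- spearman_screen(cohort[, feats], pred_all, m = length(feats),
                              alpha = config$alpha)
  structure(list(lambda = cv$lambda,
                 coefficients = cv$fit$coefficients,
                 intercept = cv$fit$intercept,
                 r2_train = scores$r2_train, r2_test = scores$r2_test,
                 aic = scores$aic, bic = scores$bic,
                 n_train = scores$n_train, n_test = scores$n_test,
                 shap_values = shap$shap,
                 base_value = shap$base_value,
                 mean_abs_shap = shap$mean_abs_shap,
                 ranking = shap$ranking,
                 spearman = spearman,
                 predictions = pred_all,
                 cv_r2 = cv$cv_r2, lambda_grid = cv$lambda_grid,
                 split_seed = seed, cv_folds = config$cv_folds,
                 config_fingerprint = config_fingerprint(config)),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> lambda = %.4g | R2 train %.3f / test %.3f | AIC %.2f BIC %.2f\n",
              x$lambda, x$r2_train, x$r2_test, x$aic, x$bic))
  cat("feature ranking by mean |SHAP|:\n")
  print(round(x$mean_abs_shap, 3))
  invisible(x)
}
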