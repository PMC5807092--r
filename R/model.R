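#' Regression fit report
#'
#' Small container for the quantities reported with every regression in the
#' pipeline: R-squared, the overall F statistic with its degrees of
#' freedom, sample size, p-value and residuals.
#'
#' @param fit an `lm` object.
#' @return a `fit_report`.
#' @export
fit_report <- function(fit) {
  sm <- summary(fit)
  fst <- sm$fstatistic
  if (is.null(fst))   # degenerate regression (constant predictor)
    fst <- c(NA_real_, sm$df[1] - 1, sm$df[2])
  structure(list(r_squared = unname(sm$r.squared),
                 f = unname(fst[1]), df1 = unname(fst[2]), df2 = unname(fst[3]),
                 n = length(stats::residuals(fit)),
                 p_value = unname(stats::pf(fst[1], fst[2], fst[3],
                                            lower.tail = FALSE)),
                 residuals = unname(stats::residuals(fit))),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("R^2 = %.3f, F(%d, %d) = %.2f, p = %.3g, n = %d\n",
              x$r_squared, x$df1, x$df2, x$f, x$p_value, x$n))
  invisible(x)
}

## report for observed-vs-predicted evaluation (df = 1, n - 2)
fit_report_obs_pred <- function(observed, predicted) {
  fit_report(stats::lm(observed ~ predicted))
}

#' Ordinary least squares of viscosity ratings on factor scores
#'
#' @param scores stimuli x factors matrix.
#' @param viscosity_ratings numeric vector, or single-column
#'   [ratings_table()] (repetition-averaged first by the caller).
#' @return list with `beta` (intercept + per-factor coefficients) and a
#'   [fit_report()] (`df2 = n - factors - 1`).
#' @export
fit_viscosity_regression <- function(scores, viscosity_ratings) {
  y <- if (inherits(viscosity_ratings, "ratings_table"))
    as.vector(viscosity_ratings$values[, 1]) else as.numeric(viscosity_ratings)
  scores <- as.matrix(scores)
  if (nrow(scores) != length(y)) stop("scores and ratings are misaligned")
  if (length(y) <= ncol(scores) + 1L) stop("too few rows for the regression")
  df <- data.frame(y = y, scores)
  fit <- stats::lm(y ~ ., data = df)
  list(beta = stats::setNames(stats::coef(fit),
                              c("(Intercept)", colnames(scores))),
       report = fit_report(fit), lm = fit)
}

#' Fit the perceptual viscosity model
#'
#' The package's core estimator: midlevel feature ratings are reduced to a
#' small number of latent factors (count chosen by Horn's parallel analysis
#' unless given), scored by the Harman method, and combined by multiple
#' linear regression into a prediction of perceived viscosity. The fitted
#' object is frozen — its loadings, score weights, standardization and
#' regression weights can be applied unchanged to ratings from entirely new
#' scene contexts via [predict()] / [evaluate_transfer()].
#'
#' @param features a [ratings_table()] of feature ratings (repetitions are
#'   averaged internally) or a stimuli x features matrix.
#' @param viscosity a single-column [ratings_table()] of viscosity ratings
#'   or a numeric vector aligned with the (averaged) feature rows.
#' @param n_factors factor count; `NULL` runs [horn_parallel_analysis()].
#' @param rotation passed to [fit_factor_model()].
#' @param horn_n_random,horn_quantile,seed parallel-analysis settings.
#' @return a `visc_model` with components `factor_model`, `beta`, `scores`,
#'   `report`, `n_factors`.
#' @examples
#' design <- set2_design()
#' truth <- make_ground_truth(design, seed = 7)
#' feats <- generate_feature_ratings(truth, repetitions = 4, seed = 7)
#' visc <- generate_viscosity_ratings(truth, repetitions = 4, seed = 7)
#' m <- visc_model(feats, visc, n_factors = 4)
#' summary(m)
#' @export
visc_model <- function(features, viscosity, n_factors = NULL,
                       rotation = "none", horn_n_random = 100L,
                       horn_quantile = 0.95, seed = 1L) {
  if (inherits(features, "ratings_table") &&
      "repetition" %in% names(features$meta))
    features <- average_repetitions(features)
  if (inherits(viscosity, "ratings_table") &&
      "repetition" %in% names(viscosity$meta))
    viscosity <- average_repetitions(viscosity)
  if (is.null(n_factors))
    n_factors <- as.integer(horn_parallel_analysis(
      features, n_random = horn_n_random, quantile = horn_quantile,
      seed = seed))
  if (n_factors < 1L)
    stop("parallel analysis retained no factors; supply n_factors explicitly")
  fm <- fit_factor_model(features, n_factors, rotation = rotation)
  sc <- factor_scores(fm, features, standardize = "training")
  reg <- fit_viscosity_regression(sc, viscosity)
  y <- if (inherits(viscosity, "ratings_table"))
    as.vector(viscosity$values[, 1]) else as.numeric(viscosity)
  structure(list(factor_model = fm, beta = reg$beta, scores = sc,
                 report = reg$report, n_factors = n_factors,
                 fitted = unname(stats::fitted(reg$lm)), observed = y,
                 meta = if (inherits(features, "ratings_table"))
                   features$meta else NULL,
                 call = match.call()),
            class = "visc_model")
}

#' @export
print.visc_model <- function(x, ...) {
  cat(sprintf("Perceptual viscosity model: %d factors from %d features\n",
              x$n_factors, length(x$factor_model$feature_names)))
  cat("Training fit: "); print(x$report)
  invisible(x)
}

#' @export
summary.visc_model <- function(object, digits = 2, ...) {
  cat("Perceptual viscosity model\n")
  cat(sprintf("  %d features -> %d factors (rotation: %s) -> viscosity\n",
              length(object$factor_model$feature_names), object$n_factors,
              object$factor_model$rotation))
  cat("\nLoadings:\n")
  L <- round(object$factor_model$loadings, digits)
  L[abs(L) < 0.1] <- 0
  print(L)
  cat("\nRegression weights:\n")
  print(round(object$beta, 3))
  cat("\nTraining fit: ")
  print(object$report)
  invisible(object)
}

#' @export
coef.visc_model <- function(object, ...) object$beta

#' @export
fitted.visc_model <- function(object, ...) object$fitted

#' @export
residuals.visc_model <- function(object, ...) object$observed - object$fitted

#' Predict viscosity ratings for new feature ratings
#'
#' Applies the frozen model: the new table is standardized (by default
#' within the new dataset — slider settings are scale-free per experiment),
#' scored with the stored Harman weights, and passed through the stored
#' regression weights. No parameter is re-estimated.
#'
#' @param object a [visc_model()].
#' @param newdata a [ratings_table()] or matrix with the training features.
#' @param standardize `"new"` (default) or `"training"`.
#' @param ... unused.
#' @return numeric vector of predicted viscosity ratings (slider units).
#' @export
predict.visc_model <- function(object, newdata,
                               standardize = c("new", "training"), ...) {
  standardize <- match.arg(standardize)
  if (inherits(newdata, "ratings_table") &&
      "repetition" %in% names(newdata$meta))
    newdata <- average_repetitions(newdata)
  sc <- factor_scores(object$factor_model, newdata, standardize = standardize)
  unname(object$beta[1] + as.vector(sc %*% object$beta[-1]))
}

#' Frozen-model transfer to a new context
#'
#' Predicts viscosity ratings for a new stimulus set with the frozen model
#' and quantifies generalization by regressing the observed ratings on the
#' predictions (`df = (1, n - 2)`).
#'
#' @param model a [visc_model()].
#' @param new_features feature [ratings_table()] from the new context.
#' @param new_viscosity observed viscosity ratings in the new context.
#' @param standardize passed to [predict.visc_model()].
#' @return list with `predictions` and `report` (a [fit_report()]).
#' @export
evaluate_transfer <- function(model, new_features, new_viscosity,
                              standardize = "new") {
  pred <- predict(model, new_features, standardize = standardize)
  if (inherits(new_viscosity, "ratings_table")) {
    if ("repetition" %in% names(new_viscosity$meta))
      new_viscosity <- average_repetitions(new_viscosity)
    new_viscosity <- as.vector(new_viscosity$values[, 1])
  }
  list(predictions = pred,
       report = fit_report_obs_pred(new_viscosity, pred))
}

#' @rdname evaluate_transfer
#' @export
predict_transfer <- evaluate_transfer

#' @export
plot.visc_model <- function(x, ...) {
  graphics::plot(x$fitted, x$observed,
                 xlab = "predicted viscosity rating",
                 ylab = "observed viscosity rating",
                 main = sprintf("Training fit (R^2 = %.2f)",
                                x$report$r_squared), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
simulate.visc_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sd_ <- stats::sd(residuals(object))
  n <- length(object$fitted)
  out <- as.data.frame(replicate(nsim, clip01(object$fitted +
                                                stats::rnorm(n, sd = sd_))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Random-predictor bootstrap baseline
#'
#' Distribution of OLS R-squared obtained by regressing the viscosity
#' ratings on `k` iid standard-normal predictors, for each `k` in
#' `n_predictors`. Quantifies how much apparent fit a given predictor count
#' buys by chance (under the null, expected R-squared is `k / (n - 1)`).
#'
#' @param viscosity_ratings numeric vector or single-column ratings table.
#' @param n_predictors integer vector of predictor counts.
#' @param n_boot bootstrap repetitions (>= 100).
#' @param seed integer seed.
#' @return data.frame with `n_predictors`, `mean_r2`, `q025`, `q975`.
#' @export
bootstrap_random_predictor_baseline <- function(viscosity_ratings,
                                                n_predictors, n_boot = 1000L,
                                                seed = 1L) {
  if (n_boot < 100L) stop("n_boot must be >= 100")
  y <- if (inherits(viscosity_ratings, "ratings_table"))
    as.vector(viscosity_ratings$values[, 1]) else as.numeric(viscosity_ratings)
  n <- length(y)
  out <- with_seed(seed, {
    do.call(rbind, lapply(n_predictors, function(k) {
      if (k >= n) stop("n_predictors must be < n")
      r2 <- vapply(seq_len(n_boot), function(b) {
        X <- matrix(stats::rnorm(n * k), n, k)
        suppressWarnings(summary(stats::lm(y ~ X))$r.squared)
      }, numeric(1))
      data.frame(n_predictors = k, mean_r2 = mean(r2),
                 q025 = unname(stats::quantile(r2, 0.025)),
                 q975 = unname(stats::quantile(r2, 0.975)))
    }))
  })
  out
}
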