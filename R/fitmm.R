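#' Fit a measurement-based viscosity model with fixed or free weights
#'
#' Multiple linear regression of viscosity ratings on one or more image or
#' mesh measurements. `fixed_across_contexts` pools all scenes with a
#' single weight set; `free_per_scene` fits each scene separately and
#' reports per-scene fits plus their mean R-squared. The free fit can never
#' be worse than the fixed fit on the training data (nesting).
#'
#' @param predictors numeric vector or stimuli x predictors matrix.
#' @param viscosity_ratings numeric vector (or single-column ratings table)
#'   aligned with `predictors`.
#' @param weights `"fixed_across_contexts"` or `"free_per_scene"`.
#' @param scene_id per-stimulus scene labels, required for the free fit.
#' @return for the fixed fit, a list with `report` ([fit_report()]) and
#'   `coefficients`; for the free fit, `per_scene` reports, `mean_r2` /
#'   `min_r2` / `max_r2` across scenes (the display convention), and
#'   `pooled_r2` (1 - pooled residual / pooled total sum of squares — the
#'   quantity that is never below the fixed fit's R-squared, since the
#'   fixed model is nested in the free one).
#' @export
fit_measurement_model <- function(predictors, viscosity_ratings,
                                  weights = c("fixed_across_contexts",
                                              "free_per_scene"),
                                  scene_id = NULL) {
  weights <- match.arg(weights)
  y <- if (inherits(viscosity_ratings, "ratings_table"))
    as.vector(viscosity_ratings$values[, 1]) else as.numeric(viscosity_ratings)
  X <- as.matrix(predictors)
  if (is.null(colnames(X))) colnames(X) <- paste0("p", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop("predictors and ratings are misaligned")
  if (weights == "fixed_across_contexts") {
    fit <- stats::lm(y ~ ., data = data.frame(y = y, X))
    return(list(mode = weights, report = fit_report(fit),
                coefficients = stats::coef(fit)))
  }
  if (is.null(scene_id)) stop("free_per_scene requires scene_id")
  scenes <- unique(scene_id)
  per <- lapply(scenes, function(s) {
    i <- scene_id == s
    fit_report(stats::lm(y ~ ., data = data.frame(y = y[i],
                                                  X[i, , drop = FALSE])))
  })
  names(per) <- scenes
  r2 <- vapply(per, function(r) r$r_squared, numeric(1))
  rss <- sum(vapply(per, function(r) sum(r$residuals^2), numeric(1)))
  tss <- sum((y - mean(y))^2)
  list(mode = weights, per_scene = per, mean_r2 = mean(r2),
       min_r2 = min(r2), max_r2 = max(r2), pooled_r2 = 1 - rss / tss)
}
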