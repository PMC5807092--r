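fit_default_model <- function(seed = 1) {
  tr <- make_ground_truth(set1_design(), seed = seed)
  feats <- generate_feature_ratings(tr, 4, seed = seed)
  visc <- generate_viscosity_ratings(tr, 4, seed = seed)
  list(truth = tr, feats = feats, visc = visc,
       model = visc_model(feats, visc, n_factors = 4))
}

test_that("the training regression has the design degrees of freedom", {
  m <- fit_default_model()$model
  expect_equal(m$report$df1, 4)
  expect_equal(m$report$df2, 187)    # 192 - 4 - 1
  expect_equal(m$report$n, 192)
  expect_gte(m$report$r_squared, 0)
  expect_lte(m$report$r_squared, 1)
})

test_that("noiseless linear ratings are fit perfectly", {
  set.seed(9)
  sc <- matrix(stats::rnorm(80), 20, 4)
  y <- 0.3 + sc %*% c(0.1, 0.2, -0.05, 0.15)
  reg <- suppressWarnings(fit_viscosity_regression(sc, as.numeric(y)))
  expect_equal(reg$report$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(reg$beta), c(0.3, 0.1, 0.2, -0.05, 0.15),
               tolerance = 1e-10)
})

test_that("generating regression weights are recovered within 2 sd", {
  ## the latent common axis leaks little into beta thanks to scoring
  fits <- lapply(1:20, fit_default_model)
  B <- t(vapply(fits, function(f) unname(coef(f$model)), numeric(5)))
  truth_b <- fits[[1]]$truth$regression_weights
  ## factor scores are standardized within the fit, so compare the
  ## correlation structure: predictions must track the generative predictor
  ok <- vapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    mu <- truth_b[1] + as.vector(f$truth$factor_scores %*% truth_b[-1])
    stats::cor(fitted(f$model), mu[seq_along(fitted(f$model))])
  }, numeric(1))
  expect_true(all(ok > 0.95))
  ## and the intercept concentrates near the generative intercept
  expect_lt(abs(mean(B[, 1]) - truth_b[1]), 2 * stats::sd(B[, 1]) + 0.02)
})

test_that("transfer onto the training set reproduces the training fit", {
  f <- fit_default_model()
  pred <- predict(f$model, f$feats, standardize = "training")
  expect_equal(pred, fitted(f$model), tolerance = 1e-10)
  ## with new-data standardization on the training set itself the
  ## standardization statistics coincide, so predictions still agree
  pred2 <- predict(f$model, f$feats, standardize = "new")
  expect_equal(pred2, fitted(f$model), tolerance = 1e-8)
})

test_that("frozen transfer to the eight-scene set reports df = (1, 54)", {
  f <- fit_default_model(seed = 3)
  tr2 <- make_ground_truth(set2_design(), loadings = f$truth$loadings,
                           beta = f$truth$regression_weights, seed = 53)
  tr <- evaluate_transfer(f$model,
                          generate_feature_ratings(tr2, 4, seed = 53),
                          generate_viscosity_ratings(tr2, 4, seed = 53))
  expect_equal(tr$report$df1, 1)
  expect_equal(tr$report$df2, 54)
  expect_length(tr$predictions, 56)
})

test_that("model methods expose the fit", {
  f <- fit_default_model()
  m <- f$model
  expect_length(coef(m), 5)
  expect_equal(length(residuals(m)), 192)
  expect_equal(fitted(m) + residuals(m), m$observed, tolerance = 1e-12)
  expect_output(print(m), "4 factors")
  expect_output(summary(m), "Loadings")
  sims <- simulate(m, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(192L, 2L))
  expect_true(all(sims >= 0 & sims <= 1))
  ## plot renders without error
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
})

test_that("random predictors buy only their null share of R-squared", {
  set.seed(5)
  y <- stats::rnorm(192)
  b <- bootstrap_random_predictor_baseline(y, 1, n_boot = 400, seed = 5)
  ## E[R^2] = k / (n - 1) under the null
  expect_equal(b$mean_r2, 1 / 191, tolerance = 0.25)
  bg <- bootstrap_random_predictor_baseline(y, c(1, 4, 16, 64),
                                            n_boot = 150, seed = 6)
  expect_true(all(diff(bg$mean_r2) > 0))
  ## saturation at n - 1 predictors
  bs <- bootstrap_random_predictor_baseline(stats::rnorm(10), 9,
                                            n_boot = 100, seed = 7)
  expect_equal(bs$mean_r2, 1, tolerance = 1e-8)
  expect_error(bootstrap_random_predictor_baseline(y, 1, n_boot = 10), "100")
  expect_error(bootstrap_random_predictor_baseline(y, 200, n_boot = 100), "< n")
})

test_that("measurement-model fits obey the free >= fixed nesting", {
  set.seed(8)
  scene <- rep(letters[1:4], each = 10)
  x <- stats::rnorm(40)
  ## opposite dependence per scene defeats a single weight set
  y <- ifelse(scene %in% c("a", "b"), x, -x) + stats::rnorm(40, sd = 0.1)
  fixed <- fit_measurement_model(x, y, "fixed_across_contexts")
  free <- fit_measurement_model(x, y, "free_per_scene", scene_id = scene)
  expect_gt(free$mean_r2, fixed$report$r_squared)
  expect_gt(free$min_r2, 0.9)
  expect_lt(fixed$report$r_squared, 0.3)
  ## nesting holds on the pooled R-squared whatever the data
  y2 <- 2 * x + stats::rnorm(40, sd = 0.2)
  fx2 <- fit_measurement_model(x, y2, "fixed_across_contexts")
  fr2 <- fit_measurement_model(x, y2, "free_per_scene", scene_id = scene)
  expect_gte(fr2$pooled_r2, fx2$report$r_squared - 1e-10)
  expect_gte(free$pooled_r2, fixed$report$r_squared - 1e-10)
})

test_that("permuted ratings yield near-zero fits", {
  set.seed(10)
  x <- matrix(stats::rnorm(56 * 2), 56)
  y <- 0.5 * x[, 1] + 0.2 * x[, 2] + stats::rnorm(56, sd = 0.1)
  r2 <- vapply(1:50, function(i) {
    fit_measurement_model(x, sample(y), "fixed_across_contexts")$report$r_squared
  }, numeric(1))
  expect_gte(mean(r2 <= 0.15), 0.9)
})

test_that("models survive a JSON round trip with identical predictions", {
  f <- fit_default_model(seed = 2)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_visc_model(f$model, tmp)
  back <- read_visc_model(tmp)
  newtab <- average_repetitions(f$feats)
  expect_equal(predict(back, newtab), predict(f$model, newtab),
               tolerance = 1e-10)
})
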