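test_that("noiseless feature tables have centered rank at most 4", {
  tr <- small_truth(noise_sd = 0)
  tab <- generate_feature_ratings(tr, repetitions = 1, seed = 1)
  sv <- svd(scale(tab$values, center = TRUE, scale = FALSE))$d
  expect_lt(sv[5] / sv[1], 1e-10)
  expect_true(all(tab$values >= 0 & tab$values <= 1))
})

test_that("noiseless repetitions are identical", {
  tr <- small_truth(noise_sd = 0)
  tab <- generate_feature_ratings(tr, repetitions = 2, seed = 1)
  n <- nrow(tr$design)
  expect_identical(tab$values[seq_len(n), ], tab$values[n + seq_len(n), ])
})

test_that("rating generators validate repetitions", {
  tr <- small_truth()
  expect_error(generate_feature_ratings(tr, repetitions = 0), "repetitions")
  expect_error(generate_viscosity_ratings(tr, repetitions = 0), "repetitions")
})

test_that("noiseless viscosity ratings are an exact affine readout", {
  tr <- small_truth(noise_sd = 0)
  tab <- generate_viscosity_ratings(tr, repetitions = 1, seed = 1)
  b <- tr$regression_weights
  mu <- b[1] + as.vector(tr$factor_scores %*% b[-1])
  expect_equal(as.vector(tab$values), pmin(1, pmax(0, mu)), tolerance = 1e-12)
  ## zero slopes give a constant column
  tr0 <- small_truth(noise_sd = 0)
  tr0$regression_weights <- c(0.4, 0, 0, 0, 0)
  tab0 <- generate_viscosity_ratings(tr0, repetitions = 1, seed = 1)
  expect_equal(as.vector(tab0$values), rep(0.4, nrow(tr0$design)))
})

test_that("monotone latent factors make ratings track log viscosity", {
  d <- set1_design()
  r2 <- vapply(1:3, function(sd) {
    tr <- make_ground_truth(d, noise_sd = 0.05, specific_sd = 0,
                            context_sd = 0, seed = sd)
    tab <- average_repetitions(generate_viscosity_ratings(tr, 4, seed = sd))
    summary(stats::lm(tab$values[, 1] ~ log10(d$viscosity)))$r.squared
  }, numeric(1))
  expect_true(all(r2 >= 0.9))
})

test_that("repetition averaging preserves design order and drops the index", {
  tr <- small_truth()
  tab <- generate_feature_ratings(tr, repetitions = 3, seed = 2)
  avg <- average_repetitions(tab)
  expect_equal(nrow(avg$values), nrow(tr$design))
  expect_equal(avg$meta$viscosity, tr$design$viscosity)
  expect_equal(avg$meta$scene_id, tr$design$scene_id)
  expect_false("repetition" %in% names(avg$meta))
  n <- nrow(tr$design)
  manual <- (tab$values[1, ] + tab$values[n + 1, ] + tab$values[2 * n + 1, ]) / 3
  expect_equal(avg$values[1, ], manual)
})

test_that("generating loadings have unit column sum of squares by default", {
  L <- block_loadings()
  expect_equal(colSums(L^2), rep(1, 4), ignore_attr = TRUE)
  Lr <- block_loadings(primary = 0.8, cross = 0, normalize = FALSE)
  expect_equal(unique(Lr[Lr != 0]), 0.8)
})

test_that("ground truth and ratings round-trip through JSON and CSV", {
  tr <- small_truth(seed = 5)
  tj <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(tr, tj)
  back <- read_ground_truth(tj)
  expect_equal(back$loadings, tr$loadings, tolerance = 1e-12)
  expect_equal(back$factor_scores, tr$factor_scores, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$regression_weights, tr$regression_weights)

  tab <- generate_feature_ratings(tr, repetitions = 2, seed = 5)
  tc <- withr::local_tempfile(fileext = ".csv")
  write_ratings_csv(tab, tc)
  tab2 <- read_ratings_csv(tc)
  expect_equal(tab2$values, tab$values, tolerance = 1e-12)
  expect_equal(tab2$meta$viscosity, tab$meta$viscosity)
})

test_that("rating tables reject out-of-range slider values", {
  expect_error(ratings_table(matrix(1.5, 2, 1), "viscosity",
                             data.frame(viscosity = c(1, 2))), "0, 1")
})
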