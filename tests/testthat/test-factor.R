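test_that("parallel analysis retains nothing on pure noise", {
  zeros <- vapply(1:20, function(sd) {
    X <- with(list(), { set.seed(1000 + sd); matrix(stats::rnorm(200 * 20), 200) })
    as.integer(horn_parallel_analysis(X, n_random = 60, seed = sd))
  }, integer(1))
  expect_gte(sum(zeros == 0L), 18L)
})

test_that("parallel analysis recovers a 4-factor structure", {
  L <- block_loadings(primary = 0.8, cross = 0, normalize = FALSE)
  ks <- vapply(1:10, function(sd) {
    tr <- iid_ground_truth(192, L, noise_sd = 0.3, seed = sd)
    tab <- generate_feature_ratings(tr, repetitions = 1, seed = sd)
    as.integer(horn_parallel_analysis(tab, n_random = 60, seed = sd))
  }, integer(1))
  expect_true(all(ks == 4L))
})

test_that("parallel analysis finds a single factor in rank-1 data", {
  set.seed(2)
  f <- stats::rnorm(150)
  X <- outer(f, stats::runif(12, 0.5, 1)) + matrix(stats::rnorm(150 * 12, sd = 0.4), 150)
  expect_equal(as.integer(horn_parallel_analysis(X, seed = 2)), 1L)
})

test_that("parallel analysis rejects constant columns and is invariant to
           permutation and affine rescaling", {
  set.seed(3)
  X <- matrix(stats::rnorm(100 * 8), 100)
  Xc <- cbind(X, 1)
  expect_error(horn_parallel_analysis(Xc, seed = 1), "constant")
  k0 <- as.integer(horn_parallel_analysis(X, seed = 4))
  perm <- X[, sample(ncol(X))]
  expect_equal(as.integer(horn_parallel_analysis(perm, seed = 4)), k0)
  resc <- sweep(sweep(X, 2, stats::runif(8, 0.5, 3), `*`), 2,
                stats::runif(8, -2, 2), `+`)
  expect_equal(as.integer(horn_parallel_analysis(resc, seed = 4)), k0)
})

test_that("the ML fit reproduces a noiseless low-rank correlation matrix", {
  L <- block_loadings(primary = 0.7, cross = 0.15, normalize = FALSE)
  tr <- iid_ground_truth(500, L, noise_sd = 0.08, seed = 11)
  tab <- generate_feature_ratings(tr, repetitions = 1, seed = 11)
  fm <- fit_factor_model(tab, 4)
  R_obs <- stats::cor(tab$values)
  R_hat <- tcrossprod(fm$loadings) + diag(fm$uniquenesses)
  expect_lt(max(abs(R_obs - R_hat)), 0.02)
  ## communalities are proper
  expect_true(all(fm$uniquenesses > 0 & fm$uniquenesses <= 1))
})

test_that("fitted loadings recover the generating structure", {
  L <- block_loadings(primary = 0.8, cross = 0, normalize = FALSE)
  congr <- vapply(1:10, function(sd) {
    tr <- iid_ground_truth(192, L, noise_sd = 0.1, seed = sd)
    tab <- generate_feature_ratings(tr, repetitions = 1, seed = sd)
    fm <- fit_factor_model(tab, 4)
    as.numeric(tucker_congruence(fm$loadings, L))
  }, numeric(1))
  expect_true(all(congr >= 0.95))
})

test_that("rotation is a post-hoc relabelling: fit quality is unchanged", {
  L <- block_loadings(primary = 0.8, cross = 0.1, normalize = FALSE)
  set.seed(21)
  Q <- qr.Q(qr(matrix(stats::rnorm(16), 4)))
  tr1 <- iid_ground_truth(300, L, noise_sd = 0.1, seed = 21)
  ## rotating loadings and counter-rotating scores leaves the data — hence
  ## the ML fit — bit-for-bit identical
  tr2 <- tr1
  tr2$loadings <- L %*% Q
  tr2$factor_scores <- tr1$factor_scores %*% Q
  t1 <- generate_feature_ratings(tr1, 1, seed = 21)
  t2 <- generate_feature_ratings(tr2, 1, seed = 21)
  expect_equal(t1$values, t2$values, tolerance = 1e-12)
  ## and the varimax flag only rotates the solution: uniquenesses and the
  ## spanned loading subspace are invariant
  f_none <- fit_factor_model(t1, 4, rotation = "none")
  f_vmax <- fit_factor_model(t1, 4, rotation = "varimax")
  expect_equal(f_none$uniquenesses, f_vmax$uniquenesses, tolerance = 1e-8)
  aligned <- procrustes_align(f_vmax$loadings, f_none$loadings)
  expect_equal(aligned, f_none$loadings, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("Harman weights are a left inverse of the loadings transpose", {
  tr <- small_truth(seed = 4)
  tab <- average_repetitions(generate_feature_ratings(tr, 4, seed = 4))
  fm <- fit_factor_model(tab, 4)
  W <- fm$score_weights
  expect_equal(t(fm$loadings) %*% W, diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  ## data lying exactly in the loading space is scored exactly
  Fm <- matrix(stats::rnorm(40), 10, 4)
  Z <- Fm %*% t(fm$loadings)
  S <- Z %*% W
  expect_equal(S, Fm, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("factor scores standardize with stored training statistics", {
  tr <- small_truth(seed = 6)
  tab <- average_repetitions(generate_feature_ratings(tr, 4, seed = 6))
  fm <- fit_factor_model(tab, 4)
  sc <- factor_scores(fm, tab, standardize = "training")
  expect_true(all(abs(colMeans(sc)) < 1e-8))
  ## an all-training-mean row scores zero
  row0 <- matrix(fm$standardization$mean, 1,
                 dimnames = list(NULL, fm$feature_names))
  expect_equal(as.numeric(factor_scores(fm, row0, "training")),
               rep(0, 4), tolerance = 1e-10)
})

test_that("feature mismatches are reported by name", {
  tr <- small_truth(seed = 6)
  tab <- average_repetitions(generate_feature_ratings(tr, 4, seed = 6))
  fm <- fit_factor_model(tab, 4)
  bad <- tab$values
  colnames(bad)[1] <- "glossiness"
  err <- tryCatch(factor_scores(fm, bad), error = conditionMessage)
  expect_match(err, "missing")
  expect_match(err, "spread")
  expect_match(err, "glossiness")
})

test_that("fit_factor_model validates the factor count", {
  tr <- small_truth(seed = 6)
  tab <- average_repetitions(generate_feature_ratings(tr, 4, seed = 6))
  expect_error(fit_factor_model(tab, 0), "n_factors")
  expect_error(fit_factor_model(tab, 20), "n_factors")
})
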