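ratings_matrix <- function(x) {
  if (inherits(x, "ratings_table")) x$values else as.matrix(x)
}

#' Horn's parallel analysis
#'
#' Retains a factor for every leading eigenvalue of the observed feature
#' correlation matrix that exceeds the chosen quantile of the matching
#' eigenvalue distribution from random standard-normal datasets of the same
#' shape. Counting stops at the first eigenvalue that falls below its
#' threshold.
#'
#' @param table a [ratings_table()] (repetition-averaged) or numeric matrix,
#'   rows = stimuli, columns = features.
#' @param n_random number of random datasets.
#' @param quantile null-distribution quantile used as the retention
#'   threshold.
#' @param seed integer seed for the random datasets.
#' @return integer retained factor count, with the observed eigenvalues and
#'   thresholds as attributes.
#' @export
horn_parallel_analysis <- function(table, n_random = 100L, quantile = 0.95,
                                   seed = 1L) {
  X <- ratings_matrix(table)
  n <- nrow(X); p <- ncol(X)
  if (p < 2L) stop("need at least 2 features")
  sds <- apply(X, 2, stats::sd)
  if (any(sds < .Machine$double.eps^0.5))
    stop("constant feature column: correlation undefined for ",
         paste(colnames(X)[sds < .Machine$double.eps^0.5], collapse = ", "))
  obs <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
  null_ev <- with_seed(seed, {
    t(vapply(seq_len(n_random), function(i) {
      R <- matrix(stats::rnorm(n * p), n, p)
      eigen(stats::cor(R), symmetric = TRUE, only.values = TRUE)$values
    }, numeric(p)))
  })
  thr <- apply(null_ev, 2, stats::quantile, probs = quantile)
  keep <- obs > thr
  k <- if (!keep[1]) 0L else which(c(!keep, TRUE))[1] - 1L
  structure(as.integer(k), eigenvalues = obs, thresholds = thr)
}

#' Maximum-likelihood factor analysis of a feature rating table
#'
#' Fits an ML factor model to the feature correlation matrix (features are
#' commensurate slider ratings but may differ in variance, so correlations
#' are used). The solution is unrotated by default; varimax (orthogonal) and
#' promax (oblique) rotations are available. Column signs follow the
#' convention that the majority of loadings per factor are non-negative.
#' Uniquenesses are bounded below at 0.005, so Heywood cases are clamped
#' (with a warning).
#'
#' The returned model stores everything needed to score new data: loadings,
#' uniquenesses, the training standardization (per-feature mean/sd), and
#' Harman idealized-variable score weights `W = L (L'L)^-1`, which are a
#' left inverse of `t(L)` — applying the loadings directly to standardized
#' data.
#'
#' @param table a [ratings_table()] or matrix (rows = stimuli).
#' @param n_factors number of factors (>= 1, < number of features).
#' @param rotation `"none"`, `"varimax"` or `"promax"`.
#' @return a `factor_model`.
#' @export
fit_factor_model <- function(table, n_factors, rotation = c("none", "varimax",
                                                            "promax")) {
  rotation <- match.arg(rotation)
  X <- ratings_matrix(table)
  p <- ncol(X)
  if (n_factors < 1L || n_factors >= p)
    stop("n_factors must be in [1, n_features)")
  if (is.null(colnames(X))) colnames(X) <- paste0("feature_", seq_len(p))
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  if (any(sd_ < .Machine$double.eps^0.5)) stop("constant feature column")
  fa <- stats::factanal(covmat = stats::cor(X), factors = n_factors,
                        n.obs = nrow(X), rotation = "none")
  L <- matrix(as.numeric(stats::loadings(fa)), p, n_factors)
  if (rotation == "varimax") {
    L <- stats::varimax(L)$loadings
    L <- matrix(as.numeric(L), p, n_factors)
  } else if (rotation == "promax") {
    L <- stats::promax(L)$loadings
    L <- matrix(as.numeric(L), p, n_factors)
  }
  ## sign convention: majority of loadings non-negative per factor
  for (k in seq_len(n_factors))
    if (mean(L[, k] >= 0) < 0.5) L[, k] <- -L[, k]
  uniq <- as.numeric(fa$uniquenesses)
  if (any(uniq <= 0.005 + 1e-12))
    warning("Heywood case: uniqueness clamped at 0.005")
  rownames(L) <- colnames(X)
  colnames(L) <- paste0("factor_", seq_len(n_factors))
  W <- L %*% solve(crossprod(L))
  dimnames(W) <- dimnames(L)
  structure(list(loadings = L, uniquenesses = stats::setNames(uniq, colnames(X)),
                 score_weights = W,
                 standardization = list(mean = mu, sd = sd_),
                 feature_names = colnames(X), n_factors = n_factors,
                 rotation = rotation,
                 factor_names = colnames(L)),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, digits = 2, ...) {
  cat(sprintf("factor_model: %d features, %d factors (rotation: %s)\n",
              length(x$feature_names), x$n_factors, x$rotation))
  cat("communalities in [", round(min(1 - x$uniquenesses), digits), ", ",
      round(max(1 - x$uniquenesses), digits), "]\n", sep = "")
  invisible(x)
}

check_features <- function(model, X) {
  have <- colnames(X)
  need <- model$feature_names
  if (is.null(have)) {
    if (ncol(X) != length(need))
      stop("feature count mismatch: expected ", length(need), ", got ", ncol(X))
    return(X[, seq_along(need), drop = FALSE])
  }
  missing_ <- setdiff(need, have)
  extra <- setdiff(have, need)
  if (length(missing_) || length(extra))
    stop("feature mismatch; missing: [",
         paste(missing_, collapse = ", "), "], extra: [",
         paste(extra, collapse = ", "), "]")
  X[, need, drop = FALSE]
}

#' Harman factor scores
#'
#' Standardizes the data and applies the stored score weights
#' `W = L (L'L)^-1`. With `standardize = "training"` the model's stored
#' training mean/sd are used (scores on the training set itself);
#' `"new"` standardizes within the supplied dataset, appropriate when
#' transferring a frozen model to ratings collected on a different slider
#' calibration.
#'
#' @param model a [fit_factor_model()] object.
#' @param table a [ratings_table()] or matrix with the model's features.
#' @param standardize `"training"` or `"new"`.
#' @return stimuli x factors score matrix.
#' @export
factor_scores <- function(model, table, standardize = c("training", "new")) {
  standardize <- match.arg(standardize)
  X <- check_features(model, ratings_matrix(table))
  if (standardize == "training") {
    Z <- sweep(sweep(X, 2, model$standardization$mean), 2,
               model$standardization$sd, `/`)
  } else {
    Z <- scale(X)
    Z[is.nan(Z)] <- 0
  }
  S <- Z %*% model$score_weights
  colnames(S) <- model$factor_names
  S
}

#' Tucker congruence between loading matrices
#'
#' Mean absolute column-wise congruence (cosine similarity) after matching
#' columns by the best permutation and sign. With `procrustes = TRUE` the
#' first matrix is first rotated onto the second by orthogonal Procrustes,
#' making the measure invariant to the rotational indeterminacy of
#' unrotated ML solutions.
#'
#' @param A,B loading matrices of equal dimension.
#' @param procrustes align `A` to `B` by orthogonal Procrustes first.
#' @return mean congruence in `[0, 1]`, per-column values as an attribute.
#' @export
tucker_congruence <- function(A, B, procrustes = TRUE) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(all(dim(A) == dim(B)))
  if (procrustes) A <- procrustes_align(A, B)
  k <- ncol(A)
  phi <- abs(crossprod(A, B) /
               outer(sqrt(colSums(A^2)), sqrt(colSums(B^2))))
  perms <- permutations(k)
  best <- -Inf; best_cols <- NULL
  for (i in seq_len(nrow(perms))) {
    v <- phi[cbind(perms[i, ], seq_len(k))]
    if (mean(v) > best) { best <- mean(v); best_cols <- v }
  }
  structure(best, per_factor = best_cols)
}

#' @rdname tucker_congruence
#' @export
procrustes_align <- function(A, B) {
  sv <- svd(crossprod(A, B))
  A %*% (sv$u %*% t(sv$v))
}

permutations <- function(k) {
  if (k == 1L) return(matrix(1L))
  sub <- permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, matrix(c(seq_len(k)[-i])[sub], nrow(sub)))
  }))
}
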