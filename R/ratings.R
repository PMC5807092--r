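#' Midlevel feature names
#'
#' Twenty midlevel shape/motion features, five per latent factor, grouped as
#' the four factors typically recovered from liquid stimuli: distribution
#' (clumping vs spreading), irregularity, rectilinearity, and dynamics.
#' @export
midlevel_features <- c(
  "spread", "compactness", "clumping", "coverage", "dispersion",
  "roughness", "complexity", "detail", "waviness", "bumpiness",
  "straightness", "angularity", "flatness", "edginess", "squareness",
  "speed", "pulsing", "wobble", "flow_activity", "splashing")

#' Block-structured factor loading matrix
#'
#' Default generating loadings: each feature loads `primary` on its block's
#' factor and `cross` on the next factor (cyclically), mirroring the simple
#' structure of empirically recovered loadings. With `normalize = TRUE`
#' columns are scaled to unit sum of squares.
#'
#' @param n_features,n_factors matrix size (features must be a multiple of
#'   factors).
#' @param primary,cross primary and cross loading values.
#' @param normalize scale columns to unit sum of squares.
#' @return `n_features` x `n_factors` matrix.
#' @export
block_loadings <- function(n_features = 20L, n_factors = 4L,
                           primary = 0.8, cross = 0.1, normalize = TRUE) {
  if (n_features %% n_factors != 0L)
    stop("n_features must be a multiple of n_factors")
  per <- n_features %/% n_factors
  L <- matrix(0, n_features, n_factors)
  for (k in seq_len(n_factors)) {
    rows <- ((k - 1L) * per + 1L):(k * per)
    L[rows, k] <- primary
    L[rows, if (k == n_factors) 1L else k + 1L] <- cross
  }
  if (normalize) L <- sweep(L, 2, sqrt(colSums(L^2)), `/`)
  rownames(L) <- if (n_features == 20L) midlevel_features else
    paste0("feature_", seq_len(n_features))
  colnames(L) <- paste0("factor_", seq_len(n_factors))
  L
}

#' Stimulus designs of the two study sets
#'
#' Set 1 is the pouring scene: 32 viscosities (0.001 to 80.3 Pa s,
#' log-spaced) crossed with 6 time periods of 1.67 s, i.e. 192 stimuli.
#' Set 2 crosses 7 viscosities (0.004 to 7.74 Pa s) with 8 scenes viewed
#' over the full 10 s, i.e. 56 stimuli.
#'
#' @return data.frame with `viscosity` (Pa s), `scene_id`, `time_period`.
#' @export
set1_design <- function() {
  v <- viscosity_grid(32, 0.001, 80.3)
  out <- expand.grid(time_period = 1:6, viscosity = v,
                     KEEP.OUT.ATTRS = FALSE)
  data.frame(viscosity = out$viscosity, scene_id = "pouring",
             time_period = as.character(out$time_period))
}

#' @rdname set1_design
#' @param scenes character vector of scene labels.
#' @export
set2_design <- function(scenes = names(default_scenes())) {
  v <- viscosity_grid(7, 0.004, 7.74)
  out <- expand.grid(scene_id = scenes, viscosity = v,
                     KEEP.OUT.ATTRS = FALSE)
  data.frame(viscosity = out$viscosity,
             scene_id = as.character(out$scene_id), time_period = "full")
}

## distinct monotone shapes in standardized log-viscosity, one per factor:
## sigmoids with staggered transition points, so each factor is monotone in
## log viscosity but becomes sensitive over a different part of the range
## (runny-regime, mid-range and viscous-regime features). Their mean is
## nearly linear in log viscosity while pairwise factor correlations stay
## well below 1, which is what lets parallel analysis resolve all four.
## Each is rescaled to unit variance over the design.
factor_shapes <- list(
  function(s) tanh(5 * (s + 1.15)),
  function(s) tanh(5 * (s + 0.4)),
  function(s) tanh(5 * (s - 0.4)),
  function(s) tanh(5 * (s - 1.15))
)

#' Generative ground truth for simulated observers
#'
#' Builds the latent structure from which rating tables are simulated: a
#' loading matrix, per-stimulus factor scores, viscosity-regression weights
#' and a rating noise level. Factor scores combine (i) a factor-specific
#' monotone function of standardized log10 viscosity, (ii) a per-context
#' (scene or time-period) offset, and (iii) viscosity-preserving
#' stimulus-specific variation: noise projected onto the contrast subspace
#' orthogonal to the mean-of-factors direction, modelling stimuli that
#' trade one midlevel quality against another (say, unusually angular but
#' correspondingly less irregular) without shifting their overall position
#' on the viscosity axis. The contrast component is what makes the four
#' factors separable while the first principal component of the feature
#' ratings stays aligned with log viscosity.
#'
#' @param design data.frame from [set1_design()] / [set2_design()].
#' @param loadings generating loading matrix (default [block_loadings()]).
#' @param beta regression weights, intercept + one per factor (slider units
#'   per factor-score unit).
#' @param noise_sd rating noise sd in slider units.
#' @param visc_weight weight of the monotone log-viscosity component.
#' @param context_sd sd of per-context factor offsets.
#' @param specific_sd sd (per contrast dimension) of the
#'   viscosity-preserving stimulus-specific factor variation; set 0 for
#'   factors exactly monotone in log viscosity.
#' @param monotone use the monotone factor shapes (otherwise factor 2 and 4
#'   get non-monotonic shapes in log viscosity).
#' @param seed integer seed.
#' @return a `ground_truth` list with `loadings`, `factor_scores`,
#'   `regression_weights`, `noise_sd`, `design`, `seed`.
#' @export
make_ground_truth <- function(design, loadings = block_loadings(),
                              beta = c(0.5, 0.09, 0.07, 0.05, 0.04),
                              noise_sd = 0.05, visc_weight = 1,
                              context_sd = 0.15, specific_sd = 1,
                              monotone = TRUE, seed = 1L) {
  n <- nrow(design)
  nf <- ncol(loadings)
  stopifnot(length(beta) == nf + 1L)
  s <- zscore_pop(log10(design$viscosity))
  shapes <- factor_shapes[seq_len(nf)]
  if (!monotone && nf >= 2L) {
    shapes[[2]] <- function(s) 1.2 * (s^2 / 2 - 0.5)
    if (nf >= 4L) shapes[[4]] <- function(s) sin(1.5 * s)
  }
  Fm <- vapply(shapes, function(g) visc_weight * zscore_pop(g(s)), numeric(n))
  ctx <- paste(design$scene_id, design$time_period)
  uctx <- unique(ctx)
  offs <- with_seed(child_seed(seed, 11L),
                    matrix(stats::rnorm(length(uctx) * nf, sd = context_sd),
                           ncol = nf, dimnames = list(uctx, NULL)))
  ## viscosity-preserving contrast noise: project onto the orthocomplement
  ## of the mean-of-factors direction
  u <- rep(1 / sqrt(nf), nf)
  proj <- diag(nf) - tcrossprod(u)
  idio <- with_seed(child_seed(seed, 12L),
                    matrix(stats::rnorm(n * nf, sd = specific_sd),
                           ncol = nf) %*% proj)
  Fm <- Fm + offs[ctx, , drop = FALSE] + idio
  dimnames(Fm) <- list(NULL, colnames(loadings))
  structure(list(loadings = loadings, factor_scores = Fm,
                 regression_weights = beta, noise_sd = noise_sd,
                 design = design, seed = seed),
            class = "ground_truth")
}

#' Rating tables
#'
#' Container mirroring an observer rating spreadsheet: a stimuli x columns
#' matrix of slider settings in `[0, 1]` plus per-row stimulus metadata
#' (viscosity, scene, time period, repetition index).
#'
#' @param values numeric matrix in `[0, 1]`.
#' @param column_names feature names or `"viscosity"`.
#' @param meta data.frame with one row per matrix row.
#' @export
ratings_table <- function(values, column_names, meta) {
  values <- as.matrix(values)
  colnames(values) <- column_names
  stopifnot(nrow(values) == nrow(meta))
  if (any(values < 0 | values > 1)) stop("ratings must lie in [0, 1]")
  structure(list(values = values, column_names = column_names, meta = meta),
            class = "ratings_table")
}

#' @export
print.ratings_table <- function(x, ...) {
  cat(sprintf("ratings_table: %d rows x %d columns (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(utils::head(x$column_names, 3), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.ratings_table <- function(x, ...) {
  cbind(x$meta, as.data.frame(x$values))
}

#' Average repetitions of a ratings table
#'
#' Collapses repeated presentations to the per-stimulus mean (the form used
#' for factor analysis and regression).
#' @param table a `ratings_table`.
#' @export
average_repetitions <- function(table) {
  key <- paste(table$meta$viscosity, table$meta$scene_id,
               table$meta$time_period)
  idx <- split(seq_along(key), factor(key, levels = unique(key)))
  nc <- ncol(table$values)
  vals <- vapply(idx, function(ii)
    colMeans(table$values[ii, , drop = FALSE]), numeric(nc))
  vals <- if (nc == 1L) matrix(vals, ncol = 1L) else t(vals)
  colnames(vals) <- colnames(table$values)
  first <- !duplicated(key)
  meta <- table$meta[first, setdiff(names(table$meta), "repetition"),
                     drop = FALSE]
  rownames(vals) <- rownames(meta) <- NULL
  ratings_table(vals, table$column_names, meta)
}

rescale_to_slider <- function(x, scale = 0.25) clip01(0.5 + scale * x)

#' Simulate observer feature ratings
#'
#' Ratings are an affine rescaling of `F %*% t(loadings)` into slider units
#' plus iid Gaussian noise per repetition, clipped to the `[0, 1]` rating
#' bar after noise.
#'
#' @param truth a [make_ground_truth()] object.
#' @param repetitions number of repeated presentations (>= 1).
#' @param seed integer seed.
#' @param rating_scale slider units per latent unit.
#' @return a [ratings_table()] with 20 feature columns and
#'   `nrow(design) * repetitions` rows.
#' @export
generate_feature_ratings <- function(truth, repetitions = 4L, seed = 1L,
                                     rating_scale = 0.25) {
  if (repetitions < 1L) stop("repetitions must be >= 1")
  X <- truth$factor_scores %*% t(truth$loadings)
  n <- nrow(X)
  rows <- vector("list", repetitions)
  for (r in seq_len(repetitions)) {
    noise <- if (truth$noise_sd > 0)
      with_seed(child_seed(seed, 100L + r),
                matrix(stats::rnorm(length(X), sd = truth$noise_sd), nrow = n))
    else 0
    rows[[r]] <- clip01(rescale_to_slider(X, rating_scale) + noise)
  }
  vals <- do.call(rbind, rows)
  meta <- do.call(rbind, lapply(seq_len(repetitions), function(r)
    cbind(truth$design, repetition = r)))
  rownames(meta) <- NULL
  ratings_table(vals, rownames(truth$loadings), meta)
}

#' Simulate observer viscosity ratings
#'
#' `clip01(beta0 + F %*% beta + noise)` per repetition: perceived viscosity
#' as a noisy linear readout of the latent factors.
#'
#' @inheritParams generate_feature_ratings
#' @export
generate_viscosity_ratings <- function(truth, repetitions = 4L, seed = 1L) {
  if (repetitions < 1L) stop("repetitions must be >= 1")
  b <- truth$regression_weights
  mu <- b[1] + as.vector(truth$factor_scores %*% b[-1])
  n <- length(mu)
  rows <- vector("list", repetitions)
  for (r in seq_len(repetitions)) {
    noise <- if (truth$noise_sd > 0)
      with_seed(child_seed(seed, 200L + r), stats::rnorm(n, sd = truth$noise_sd))
    else 0
    rows[[r]] <- clip01(mu + noise)
  }
  vals <- matrix(unlist(rows), ncol = 1)
  meta <- do.call(rbind, lapply(seq_len(repetitions), function(r)
    cbind(truth$design, repetition = r)))
  rownames(meta) <- NULL
  ratings_table(vals, "viscosity", meta)
}

#' Ground-truth JSON round trip
#' @param truth a `ground_truth`.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(loadings = truth$loadings, factor_scores = truth$factor_scores,
              regression_weights = truth$regression_weights,
              noise_sd = truth$noise_sd, design = truth$design,
              seed = truth$seed,
              feature_names = rownames(truth$loadings))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- as.matrix(obj$loadings)
  rownames(L) <- obj$feature_names
  colnames(L) <- paste0("factor_", seq_len(ncol(L)))
  structure(list(loadings = L, factor_scores = as.matrix(obj$factor_scores),
                 regression_weights = as.numeric(obj$regression_weights),
                 noise_sd = obj$noise_sd,
                 design = as.data.frame(obj$design), seed = obj$seed),
            class = "ground_truth")
}

#' Ratings CSV round trip
#' @param table a `ratings_table`.
#' @param path file path.
#' @export
write_ratings_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings_csv
#' @param feature_columns names of rating columns; remaining columns are
#'   treated as metadata.
#' @export
read_ratings_csv <- function(path, feature_columns = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(feature_columns))
    feature_columns <- setdiff(names(df), c("viscosity", "scene_id",
                                            "time_period", "repetition"))
  meta <- df[, setdiff(names(df), feature_columns), drop = FALSE]
  ratings_table(as.matrix(df[, feature_columns, drop = FALSE]),
                feature_columns, meta)
}
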