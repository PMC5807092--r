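#' Pixel-space PCA of video stimuli (Gram-matrix route)
#'
#' Represents each stimulus by its raw grayscale pixel values: frames are
#' converted to grayscale (if RGB), halved by 2x2 averaging down to
#' `target_resolution` when supplied at double size, and flattened into one
#' vector of length `width x height x frames` (e.g. 400 x 300 x 300 = 36
#' million dimensions per stimulus). Because dimensions vastly outnumber
#' stimuli, the PCA is computed from the n x n Gram matrix of the
#' dimension-centered data, which yields the same scores as a direct
#' covariance PCA. There are at most n - 1 nonzero components.
#'
#' @param videos list of `silhouette_video` objects or h x w x frames
#'   arrays (one per stimulus), all with identical dimensions.
#' @param target_resolution `c(width, height)` after halving; `NULL` keeps
#'   the input size.
#' @return a `pca_result`: `scores` (n x k), `explained` (non-increasing
#'   variance fractions), `sdev`.
#' @export
pixel_pca <- function(videos, target_resolution = NULL) {
  vecs <- lapply(videos, function(v) {
    a <- if (inherits(v, "silhouette_video")) v$intensity else v
    if (length(dim(a)) == 4L) {   # RGB frames
      a <- vapply(seq_len(dim(a)[4]), function(f) rgb_to_gray(a[, , , f]),
                  matrix(0, dim(a)[1], dim(a)[2]))
    }
    if (!is.null(target_resolution)) {
      w <- target_resolution[1]; h <- target_resolution[2]
      if (ncol(a[, , 1]) == 2L * w && nrow(a[, , 1]) == 2L * h) {
        a <- vapply(seq_len(dim(a)[3]), function(f) halve_image(a[, , f]),
                    matrix(0, h, w))
      } else if (ncol(a[, , 1]) != w || nrow(a[, , 1]) != h) {
        stop("frames must be at target resolution or exactly double it")
      }
    }
    as.vector(a)
  })
  lens <- lengths(vecs)
  if (length(unique(lens)) != 1L)
    stop("stimuli differ in frame count or resolution")
  X <- do.call(rbind, vecs)               # n x p
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))          # center each dimension
  G <- tcrossprod(Xc)
  eg <- eigen(G, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  k <- sum(ev > max(ev) * 1e-10)
  scores <- eg$vectors[, seq_len(k), drop = FALSE] *
    rep(sqrt(ev[seq_len(k)]), each = n)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, explained = ev[seq_len(k)] / sum(ev),
                 sdev = sqrt(ev[seq_len(k)] / (n - 1)), loadings = NULL),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d stimuli, %d components; PC1 explains %.1f%%\n",
              nrow(x$scores), ncol(x$scores), 100 * x$explained[1]))
  invisible(x)
}

#' Feature-space PCA of a rating table
#'
#' PCA of the standardized (z-scored) feature matrix. When viscosity labels
#' are available the sign of PC1 is fixed so that it correlates positively
#' with log10 viscosity.
#'
#' @param table a [ratings_table()] (repetition-averaged internally) or
#'   stimuli x features matrix.
#' @param viscosities optional Pa s labels; taken from the table metadata
#'   when present.
#' @return a `pca_result` with `scores`, `loadings`, `explained`, `sdev`.
#' @export
feature_pca <- function(table, viscosities = NULL) {
  if (inherits(table, "ratings_table")) {
    if ("repetition" %in% names(table$meta)) table <- average_repetitions(table)
    if (is.null(viscosities)) viscosities <- table$meta$viscosity
    X <- table$values
  } else X <- as.matrix(table)
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  scores <- pc$x
  loadings <- pc$rotation
  if (!is.null(viscosities)) {
    r <- stats::cor(scores[, 1], log10(viscosities))
    if (!is.na(r) && r < 0) {
      scores[, 1] <- -scores[, 1]
      loadings[, 1] <- -loadings[, 1]
    }
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loadings, explained = expl,
                 sdev = pc$sdev), class = "pca_result")
}

#' Alignment of the first principal component with physical viscosity
#'
#' OLS of the PC1 score on log10 viscosity (the stimuli are log-spaced;
#' an ordinal-rank axis is available as an alternative), with
#' `df = (1, n - 2)`.
#'
#' @param pca a `pca_result`.
#' @param viscosities Pa s labels aligned with the scores.
#' @param axis `"log"` or `"ordinal"`.
#' @return a [fit_report()].
#' @export
viscosity_alignment <- function(pca, viscosities, axis = c("log", "ordinal")) {
  axis <- match.arg(axis)
  x <- if (axis == "log") log10(viscosities) else rank(viscosities)
  fit_report(stats::lm(pca$scores[, 1] ~ x))
}
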