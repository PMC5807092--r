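#' Representational dissimilarity matrix in factor space
#'
#' Pairwise Euclidean distances between stimuli in the (4-D) factor-score
#' space. The result satisfies the metric axioms (symmetry, zero diagonal,
#' non-negativity, triangle inequality) and is invariant to orthogonal
#' rotation of the factor space.
#'
#' @param scores stimuli x factors matrix.
#' @param labels optional stimulus labels.
#' @return an `rdm`: n x n numeric matrix with labels as dimnames.
#' @export
compute_rdm <- function(scores, labels = NULL) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L) stop("need at least 2 stimuli")
  d <- as.matrix(stats::dist(scores))
  if (!is.null(labels)) dimnames(d) <- list(labels, labels)
  structure(d, class = c("rdm", class(d)))
}

#' Compare two RDMs by lower-triangle regression
#'
#' OLS regression of `b`'s strictly-lower-triangle entries on `a`'s (the
#' diagonal and upper triangle are excluded), giving `n(n-1)/2` pairs and
#' `df2 = pairs - 2`. With an intercept the R-squared is symmetric in the
#' two matrices.
#'
#' @param a,b `rdm` matrices of equal size with matching labels.
#' @return a [fit_report()].
#' @export
compare_rdms <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("RDMs differ in size")
  la <- rownames(a); lb <- rownames(b)
  if (!is.null(la) && !is.null(lb) && !identical(la, lb))
    stop("RDM labels do not match")
  lt <- lower.tri(a)
  fit_report(stats::lm(b[lt] ~ a[lt]))
}
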