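#' Per-vertex principal curvatures by local quadric fitting
#'
#' Estimates the second fundamental form at each vertex by least-squares
#' fitting a quadric height function over the k-ring neighborhood expressed
#' in the vertex tangent frame, then solving the shape operator for the
#' principal curvatures. The sign convention makes convex regions positive:
#' a sphere of radius r has k1 = k2 = 1/r with outward normals.
#'
#' Boundary vertices and vertices with fewer than 5 usable neighbors are
#' flagged undefined and excluded from all curvature integrals.
#'
#' @param mesh a `mesh_frame`.
#' @param neighborhood_rings ring count for the fitting neighborhood
#'   (2 is robust on irregular liquid meshes).
#' @return a `curvature_field`: list with per-vertex `k1 >= k2` (1/m), mean
#'   curvature `H`, Gaussian curvature `K`, Koenderink shape index `S` in
#'   `[-1, 1]`, mixed `area` weights (m^2), unit `normals`, and a `defined`
#'   logical vector.
#' @export
principal_curvatures <- function(mesh, neighborhood_rings = 2L) {
  stopifnot(inherits(mesh, "mesh_frame"), neighborhood_rings >= 1L)
  v <- mesh$vertices
  n <- nrow(v)
  if (n < 1L) stop("empty mesh")
  nb1 <- vertex_neighbors(mesh)
  normals <- vertex_normals(mesh)
  areas <- vertex_areas(mesh)
  bnd <- boundary_vertices(mesh)

  nb <- nb1
  if (neighborhood_rings >= 2L) {
    for (r in seq_len(neighborhood_rings - 1L)) {
      nb <- lapply(seq_len(n), function(i) {
        ext <- unlist(nb1[nb[[i]]], use.names = FALSE)
        setdiff(unique(c(nb[[i]], ext)), i)
      })
    }
  }

  k1 <- k2 <- rep(NA_real_, n)
  defined <- !bnd
  for (i in seq_len(n)) {
    if (!defined[i]) next
    idx <- nb[[i]]
    if (length(idx) < 5L) { defined[i] <- FALSE; next }
    nv <- normals[i, ]
    ## tangent basis orthogonal to the vertex normal
    a <- if (abs(nv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    t1 <- a - sum(a * nv) * nv
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(nv[2] * t1[3] - nv[3] * t1[2],
            nv[3] * t1[1] - nv[1] * t1[3],
            nv[1] * t1[2] - nv[2] * t1[1])
    d <- sweep(v[idx, , drop = FALSE], 2, v[i, ], `-`)
    u <- d %*% t1; w <- d %*% t2; z <- d %*% nv
    X <- cbind(u, w, 0.5 * u^2, u * w, 0.5 * w^2)
    XtX <- crossprod(X)
    cf <- tryCatch(solve(XtX, crossprod(X, z)), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) { defined[i] <- FALSE; next }
    D <- cf[1]; E <- cf[2]; A <- cf[3]; B <- cf[4]; C <- cf[5]
    s <- sqrt(1 + D^2 + E^2)
    ## shape operator I^-1 II of the fitted graph; its eigenvalues are real
    e11 <- 1 + D^2; e12 <- D * E; e22 <- 1 + E^2
    deti <- e11 * e22 - e12^2
    w11 <- (e22 * A - e12 * B) / (deti * s)
    w12 <- (e22 * B - e12 * C) / (deti * s)
    w21 <- (e11 * B - e12 * A) / (deti * s)
    w22 <- (e11 * C - e12 * B) / (deti * s)
    tr <- w11 + w22
    disc <- sqrt(max(0, tr^2 - 4 * (w11 * w22 - w12 * w21)))
    ## flip so convex-with-outward-normal is positive
    k1[i] <- -(tr - disc) / 2
    k2[i] <- -(tr + disc) / 2
  }

  fld <- structure(list(k1 = k1, k2 = k2, H = (k1 + k2) / 2, K = k1 * k2,
                        S = NULL, area = areas, normals = normals,
                        defined = defined, boundary = bnd),
                   class = "curvature_field")
  fld$S <- shape_index(fld)
  fld
}

#' Koenderink shape index
#'
#' `S = (2/pi) atan((k1 + k2) / (k1 - k2))` with `k1 >= k2`, classifying
#' local surface type on `[-1, 1]`: -1 cup, -0.5 rut, 0 saddle, +0.5 ridge,
#' +1 cap. At umbilic points (`|k1 - k2| < tol`) the limit `sign(H)` is
#' used, and S = 0 when both curvatures vanish.
#'
#' @param field a `curvature_field`.
#' @param tol umbilic tolerance (1/m).
#' @return per-vertex shape index (NA where curvature is undefined).
#' @export
shape_index <- function(field, tol = 1e-9) {
  k1 <- field$k1; k2 <- field$k2
  H <- (k1 + k2) / 2
  S <- rep(NA_real_, length(k1))
  ok <- !is.na(k1)
  umb <- ok & abs(k1 - k2) < tol
  flat <- umb & abs(k1) < tol & abs(k2) < tol
  reg <- ok & !umb
  S[reg] <- (2 / pi) * atan((k1[reg] + k2[reg]) / (k1[reg] - k2[reg]))
  S[umb] <- sign(H[umb])
  S[flat] <- 0
  S
}

#' @export
print.curvature_field <- function(x, ...) {
  cat(sprintf("curvature_field: %d vertices (%d defined, %d boundary)\n",
              length(x$k1), sum(x$defined), sum(x$boundary)))
  invisible(x)
}
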