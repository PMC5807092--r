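#' Four 3D shape measurements of a liquid mesh
#'
#' The four per-frame mesh statistics used as the physical comparison model:
#'
#' * `metric_angular_curvature` (M1): area-weighted mean of `|H| * w(S)` —
#'   mean absolute curvature weighted by the shape index, emphasizing
#'   angular features (caps, cups, ridges and ruts over saddles). The
#'   default weighting is `w(S) = |S|`; pluggable for sensitivity analysis.
#' * `metric_flatness` (M2): area-weighted sum of `|n . z|` over vertex
#'   normals — large where the liquid forms horizontal planes.
#' * `metric_com_height` (M3): z of the volume centroid (signed-tetrahedron
#'   decomposition) for watertight meshes; area-weighted surface centroid as
#'   a flagged fallback for open sheets. High when the liquid piles up.
#' * `metric_total_abs_curvature` (M4): integral of `|K|` (total absolute
#'   Gaussian curvature) — large for convoluted surfaces; 4*pi on any
#'   sphere, 8*pi on a torus. A `|H|` variant is available behind a flag.
#'
#' M1 and M4 integrate over defined (interior) vertices only; M2 uses every
#' vertex with a computable normal.
#'
#' @param field a [principal_curvatures()] field.
#' @param weighting function of the shape index used in M1.
#' @return scalar metric value (`NA` if no vertex has defined curvature).
#' @name metrics3d
NULL

#' @rdname metrics3d
#' @export
metric_angular_curvature <- function(field, weighting = abs) {
  ok <- field$defined & !is.na(field$H)
  if (!any(ok)) return(NA_real_)
  w <- field$area[ok]
  sum(w * abs(field$H[ok]) * weighting(field$S[ok])) / sum(w)
}

#' @rdname metrics3d
#' @param mesh a `mesh_frame` (M2, M3).
#' @export
metric_flatness <- function(mesh, field = NULL) {
  if (is.null(field)) {
    nz <- vertex_normals(mesh)[, 3]
    w <- vertex_areas(mesh)
  } else {
    nz <- field$normals[, 3]
    w <- field$area
  }
  sum(w * abs(nz))
}

#' @rdname metrics3d
#' @export
metric_com_height <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  closed <- !any(boundary_vertices(mesh))
  if (closed) {
    a <- v[f[, 1], , drop = FALSE]
    b <- v[f[, 2], , drop = FALSE]
    cc <- v[f[, 3], , drop = FALSE]
    detv <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
            a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
            a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
    vol <- sum(detv) / 6
    if (abs(vol) > 1e-12) {
      zc <- sum(detv * (a[, 3] + b[, 3] + cc[, 3]) / 4) / 6 / vol
      return(structure(zc, watertight = TRUE))
    }
  }
  ## open or degenerate: area-weighted surface centroid, flagged
  fa <- face_areas(v, f)
  zc <- sum(fa * (v[f[, 1], 3] + v[f[, 2], 3] + v[f[, 3], 3]) / 3) / sum(fa)
  structure(zc, watertight = FALSE)
}

#' @rdname metrics3d
#' @param use_mean_curvature use `|H|` instead of `|K|` in M4.
#' @export
metric_total_abs_curvature <- function(field, use_mean_curvature = FALSE) {
  ok <- field$defined & !is.na(field$K)
  if (!any(ok)) return(NA_real_)
  q <- if (use_mean_curvature) abs(field$H[ok]) else abs(field$K[ok])
  sum(field$area[ok] * q)
}

#' All four metrics for one mesh frame
#'
#' @param mesh a `mesh_frame`.
#' @param neighborhood_rings passed to [principal_curvatures()].
#' @return named numeric vector `m1..m4`.
#' @export
frame_metrics <- function(mesh, neighborhood_rings = 2L) {
  fld <- principal_curvatures(mesh, neighborhood_rings)
  c(m1_angular_curvature = metric_angular_curvature(fld),
    m2_flatness = metric_flatness(mesh, fld),
    m3_com_height = as.numeric(metric_com_height(mesh)),
    m4_total_abs_curvature = metric_total_abs_curvature(fld))
}

#' Per-stimulus 3D metric vectors with temporal and between-stimulus
#' normalization
#'
#' Aggregates per-frame metrics into one row per stimulus (or per stimulus
#' and time period) and applies the two normalizations used before model
#' fitting: `per_time_period` takes the median within each of `n_periods`
#' equal slices and divides by the across-period median per stimulus, which
#' compensates for large changes in mesh size over time; `full_sequence`
#' simply averages all frames. In both modes each metric is finally
#' z-normalized (mean 0, unit sample sd) across the stimulus set.
#'
#' @param seqs list of `mesh_sequence` objects (one per stimulus), or a list
#'   of per-frame metric matrices as returned by [frame_metrics()] rows.
#' @param aggregation `"full_sequence"` or `"per_time_period"`.
#' @param n_periods number of equal time slices (6 slices of 1.67 s for the
#'   full 10 s stimuli).
#' @param frame_stride compute metrics every `frame_stride`-th frame.
#' @param neighborhood_rings passed to [principal_curvatures()].
#' @return data.frame with stimulus metadata, raw aggregated `m1..m4` and
#'   z-normalized `m1_z..m4_z` columns.
#' @export
extract_metrics <- function(seqs, aggregation = c("full_sequence", "per_time_period"),
                            n_periods = 6L, frame_stride = 1L,
                            neighborhood_rings = 2L) {
  aggregation <- match.arg(aggregation)
  per_frame <- lapply(seqs, function(s) {
    if (is.matrix(s)) return(s)
    stopifnot(inherits(s, "mesh_sequence"))
    idx <- seq(1L, length(s$frames), by = frame_stride)
    t(vapply(s$frames[idx], frame_metrics, numeric(4),
             neighborhood_rings = neighborhood_rings))
  })
  meta <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    if (inherits(s, "mesh_sequence"))
      data.frame(stimulus_id = i, viscosity = s$viscosity,
                 scene_id = s$scene$scene_id)
    else data.frame(stimulus_id = i, viscosity = NA_real_, scene_id = NA_character_)
  })

  if (aggregation == "full_sequence") {
    agg <- t(vapply(per_frame, colMeans, numeric(4), na.rm = TRUE))
    out <- cbind(do.call(rbind, meta), time_period = "full",
                 as.data.frame(agg))
  } else {
    rows <- list()
    for (i in seq_along(per_frame)) {
      pm <- per_frame[[i]]
      nf <- nrow(pm)
      if (nf < n_periods) stop("fewer frames than time periods")
      cut_id <- cut(seq_len(nf), n_periods, labels = FALSE)
      med <- apply(pm, 2, function(col) tapply(col, cut_id, stats::median, na.rm = TRUE))
      ## compensate mesh-size drift: divide by the across-period median
      fam <- apply(med, 2, stats::median, na.rm = TRUE)
      fam[!is.finite(fam) | abs(fam) < 1e-12] <- 1
      med <- sweep(med, 2, fam, `/`)
      rows[[i]] <- cbind(meta[[i]][rep(1, n_periods), , drop = FALSE],
                         time_period = seq_len(n_periods),
                         as.data.frame(med))
    }
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  mcols <- c("m1_angular_curvature", "m2_flatness", "m3_com_height",
             "m4_total_abs_curvature")
  names(out)[(ncol(out) - 3):ncol(out)] <- mcols
  if (nrow(out) < 2L) stop("z-normalization needs at least 2 stimuli")
  for (m in mcols) {
    s <- stats::sd(out[[m]])
    if (!is.finite(s) || s == 0)
      stop("zero variance across stimuli in ", m, ": degenerate design")
    out[[paste0(m, "_z")]] <- (out[[m]] - mean(out[[m]])) / s
  }
  out
}
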