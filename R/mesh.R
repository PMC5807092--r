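#' Triangle mesh frame
#'
#' Minimal triangle-mesh container: an n x 3 vertex matrix (meters, +z up)
#' and an m x 3 integer face matrix with counter-clockwise winding (outward
#' normals where the mesh is closed). Degenerate (zero-area) faces are
#' dropped at construction.
#'
#' @param vertices numeric n x 3 matrix.
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @return a `mesh_frame`.
#' @export
mesh_frame <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3)
  if (nrow(faces) > 0) {
    if (max(faces) > nrow(vertices) || min(faces) < 1L)
      stop("face indices out of range")
    a <- face_areas(vertices, faces)
    faces <- faces[a > 1e-14 * max(a, 1e-300), , drop = FALSE]
  }
  structure(list(vertices = vertices, faces = faces, up_axis = "+z"),
            class = "mesh_frame")
}

face_areas <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

face_normals <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm / pmax(len, 1e-300)
}

## area-weighted vertex normals
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  fn <- face_normals(v, f)
  fa <- face_areas(v, f)
  vn <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    vn[, 1] <- vn[, 1] + tabulate_weighted(f[, k], fn[, 1] * fa, nrow(v))
    vn[, 2] <- vn[, 2] + tabulate_weighted(f[, k], fn[, 2] * fa, nrow(v))
    vn[, 3] <- vn[, 3] + tabulate_weighted(f[, k], fn[, 3] * fa, nrow(v))
  }
  len <- sqrt(rowSums(vn^2))
  vn / pmax(len, 1e-300)
}

tabulate_weighted <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

## barycentric mixed area: one third of incident face area per vertex
vertex_areas <- function(mesh) {
  fa <- face_areas(mesh$vertices, mesh$faces)
  n <- nrow(mesh$vertices)
  out <- numeric(n)
  for (k in 1:3) out <- out + tabulate_weighted(mesh$faces[, k], fa / 3, n)
  out
}

## vertices on an open boundary (incident to an edge with a single face)
boundary_vertices <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  open_e <- e[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
  out <- logical(nrow(mesh$vertices))
  out[unique(as.vector(open_e))] <- TRUE
  out
}

## one-ring adjacency as a list of integer vectors
vertex_neighbors <- function(mesh) {
  f <- mesh$faces
  n <- nrow(mesh$vertices)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)],
             f[, c(2, 1)], f[, c(3, 2)], f[, c(1, 3)])
  e <- unique(e)
  split(e[, 2], factor(e[, 1], levels = seq_len(n)))
}

#' Triangulate a height field into a grid mesh
#'
#' @param h grid_n x grid_n matrix of heights (m).
#' @param dx cell size (m).
#' @return a `mesh_frame` over the full domain (open sheet).
#' @export
heightfield_mesh <- function(h, dx) {
  n <- nrow(h)
  xs <- (seq_len(n) - 0.5) * dx
  v <- cbind(rep(xs, times = n), rep(xs, each = n), as.vector(h))
  idx <- function(i, j) (j - 1L) * n + i
  i <- rep(seq_len(n - 1L), times = n - 1L)
  j <- rep(seq_len(n - 1L), each = n - 1L)
  ## two CCW triangles per cell, normals pointing +z for a flat sheet
  f1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
  f2 <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  mesh_frame(v, rbind(f1, f2))
}

#' Write and read Wavefront OBJ meshes
#'
#' Plain-text OBJ with `v`/`f` records only; one file per frame with a
#' zero-padded frame index when writing a sequence.
#'
#' @param mesh a `mesh_frame`.
#' @param path file path.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' @rdname write_obj
#' @param path file path to read.
#' @export
read_obj <- function(path) {
  ln <- readLines(path)
  vs <- ln[startsWith(ln, "v ")]
  fs <- ln[startsWith(ln, "f ")]
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vs)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fs)), "\\s+"),
                             function(x) as.integer(sub("/.*", "", x[1:3]))))
  mesh_frame(v, f)
}

#' @rdname write_obj
#' @param seq a `mesh_sequence`.
#' @param dir output directory (created if needed).
#' @export
write_obj_sequence <- function(seq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(seq$frames))
    write_obj(seq$frames[[i]], file.path(dir, sprintf("frame_%04d.obj", i)))
  invisible(dir)
}

# ---- analytic fixtures ------------------------------------------------------

#' Analytic mesh fixtures
#'
#' Meshes with known differential geometry, used to validate the curvature
#' and metric estimators: an icosphere (subdivided icosahedron projected to
#' the sphere), a capped or open cylinder, a torus, a saddle patch and a box.
#'
#' @param subdiv icosphere subdivision level (4 gives 2562 vertices).
#' @param radius,center sphere radius and center.
#' @return a `mesh_frame`.
#' @export
icosphere <- function(subdiv = 3L, radius = 1, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(hash = TRUE)
    nf <- matrix(0L, 0, 3)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      got <- mid_cache[[key]]
      if (!is.null(got)) return(got)
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    out <- vector("list", nrow(f))
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      out[[i]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca))
    }
    f <- do.call(rbind, out)
  }
  mesh_frame(sweep(v * radius, 2, center, `+`), f)
}

#' @rdname icosphere
#' @param n_theta,n_z angular and axial resolution.
#' @param height cylinder height.
#' @export
cylinder_mesh <- function(radius = 1, height = 4, n_theta = 64L, n_z = 32L) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  zs <- seq(-height / 2, height / 2, length.out = n_z)
  v <- cbind(radius * cos(rep(th, times = n_z)),
             radius * sin(rep(th, times = n_z)),
             rep(zs, each = n_theta))
  idx <- function(i, j) (j - 1L) * n_theta + i
  i <- rep(seq_len(n_theta), times = n_z - 1L)
  j <- rep(seq_len(n_z - 1L), each = n_theta)
  ip <- ifelse(i == n_theta, 1L, i + 1L)
  f <- rbind(cbind(idx(i, j), idx(ip, j), idx(ip, j + 1L)),
             cbind(idx(i, j), idx(ip, j + 1L), idx(i, j + 1L)))
  mesh_frame(v, f)
}

#' @rdname icosphere
#' @param R,r major and minor torus radii.
#' @param n_u,n_v toroidal and poloidal resolution.
#' @export
torus_mesh <- function(R = 2, r = 0.5, n_u = 72L, n_v = 36L) {
  u <- seq(0, 2 * pi, length.out = n_u + 1L)[-(n_u + 1L)]
  vv <- seq(0, 2 * pi, length.out = n_v + 1L)[-(n_v + 1L)]
  uu <- rep(u, times = n_v); ww <- rep(vv, each = n_u)
  v <- cbind((R + r * cos(ww)) * cos(uu),
             (R + r * cos(ww)) * sin(uu),
             r * sin(ww))
  idx <- function(i, j) (j - 1L) * n_u + i
  i <- rep(seq_len(n_u), times = n_v)
  j <- rep(seq_len(n_v), each = n_u)
  ip <- ifelse(i == n_u, 1L, i + 1L)
  jp <- ifelse(j == n_v, 1L, j + 1L)
  f <- rbind(cbind(idx(i, j), idx(ip, j), idx(ip, jp)),
             cbind(idx(i, j), idx(ip, jp), idx(i, jp)))
  mesh_frame(v, f)
}

#' @rdname icosphere
#' @param a,b saddle coefficients of `z = a x^2 - b y^2`.
#' @param half_width patch half-width; `n` grid resolution per side.
#' @export
saddle_mesh <- function(a = 1, b = 1, half_width = 0.5, n = 41L) {
  xs <- seq(-half_width, half_width, length.out = n)
  v <- cbind(rep(xs, times = n), rep(xs, each = n), 0)
  v[, 3] <- a * v[, 1]^2 - b * v[, 2]^2
  idx <- function(i, j) (j - 1L) * n + i
  i <- rep(seq_len(n - 1L), times = n - 1L)
  j <- rep(seq_len(n - 1L), each = n - 1L)
  f <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
             cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  mesh_frame(v, f)
}

#' @rdname icosphere
#' @param lo,hi opposite box corners.
#' @export
box_mesh <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  g <- expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]), z = c(lo[3], hi[3]))
  v <- as.matrix(g)
  ## 12 triangles, outward winding
  f <- rbind(c(1, 3, 7), c(1, 7, 5),   # x = lo
             c(2, 8, 4), c(2, 6, 8),   # x = hi
             c(1, 5, 6), c(1, 6, 2),   # y = lo
             c(3, 4, 8), c(3, 8, 7),   # y = hi
             c(1, 2, 4), c(1, 4, 3),   # z = lo
             c(5, 7, 8), c(5, 8, 6))   # z = hi
  mesh_frame(v, f)
}

#' @rdname icosphere
#' @param h cone height; base (radius `radius`) sits at z = 0.
#' @param n_theta angular resolution.
#' @export
cone_mesh <- function(radius = 1, h = 1, n_theta = 96L) {
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  rim <- cbind(radius * cos(th), radius * sin(th), 0)
  v <- rbind(rim, c(0, 0, h), c(0, 0, 0))   # apex, base center
  apex <- n_theta + 1L; ctr <- n_theta + 2L
  nxt <- c(seq_len(n_theta)[-1], 1L)
  f <- rbind(cbind(seq_len(n_theta), nxt, apex),        # side, outward
             cbind(nxt, seq_len(n_theta), ctr))         # base, downward
  mesh_frame(v, f)
}
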