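#' Orthographic silhouette rendering
#'
#' Renders a mesh sequence from the side (viewing along -y, x right, z up)
#' into grayscale frames. Each liquid pixel's intensity is proportional to
#' the depth extent of the surface along the viewing ray (thicker bodies
#' appear brighter); pixels covered by a single thin sheet receive one depth
#' quantum so the liquid mask is exactly the set of pixels with positive
#' intensity. Background is 0. A binary mask per frame is returned
#' alongside the intensities.
#'
#' @param seq a `mesh_sequence` (or list of `mesh_frame`s).
#' @param resolution `c(width, height)` in pixels, 4:3 aspect
#'   (default 800 x 600, the stimulus render size).
#' @param window world window `list(x = c(lo, hi), z = c(lo, hi))`; for a
#'   simulated sequence it defaults to the domain width with matching
#'   aspect (square pixels).
#' @return a `silhouette_video`: list with `intensity` and `mask`
#'   (height x width x frames arrays; row 1 = top), `resolution`, `window`.
#' @export
render_silhouette <- function(seq, resolution = c(800, 600), window = NULL) {
  w <- as.integer(resolution[1]); h <- as.integer(resolution[2])
  if (abs(w / h - 4 / 3) > 1e-6)
    stop("resolution must have 4:3 aspect")
  frames <- if (inherits(seq, "mesh_sequence")) seq$frames else seq
  if (is.null(window)) {
    if (inherits(seq, "mesh_sequence")) {
      ds <- seq$scene$domain_size
      window <- list(x = c(0, ds), z = c(0, ds * h / w))
    } else {
      vv <- do.call(rbind, lapply(frames, function(m) m$vertices))
      if (is.null(vv) || nrow(vv) == 0) {
        window <- list(x = c(0, 1), z = c(0, 0.75))
      } else {
        cx <- mean(range(vv[, 1])); cz <- mean(range(vv[, 3]))
        half_w <- max(diff(range(vv[, 1])), diff(range(vv[, 3])) * w / h) * 0.55
        window <- list(x = cx + c(-1, 1) * half_w,
                       z = cz + c(-1, 1) * half_w * h / w)
      }
    }
  }
  intensity <- array(0, dim = c(h, w, length(frames)))
  mask <- array(FALSE, dim = c(h, w, length(frames)))
  quantum <- diff(window$x) / w        # one pixel's worth of depth
  for (fi in seq_along(frames)) {
    r <- rasterize_depth(frames[[fi]], w, h, window)
    m <- r$covered
    d <- r$ymax - r$ymin
    d[m] <- pmax(d[m], quantum)
    d[!m] <- 0
    intensity[, , fi] <- d
    mask[, , fi] <- m
  }
  structure(list(intensity = intensity, mask = mask,
                 resolution = c(w, h), window = window),
            class = "silhouette_video")
}

## rasterize one mesh frame in orthographic side view; returns per-pixel
## covered flag and min/max depth (y) among covering triangles. Besides
## barycentric pixel-center coverage, triangle edges are splatted onto
## their nearest pixels so sheets thinner than a pixel still register.
rasterize_depth <- function(mesh, w, h, window) {
  ymin <- matrix(Inf, h, w); ymax <- matrix(-Inf, h, w)
  covered <- matrix(FALSE, h, w)
  f <- mesh$faces
  if (is.null(f) || nrow(f) == 0)
    return(list(covered = covered, ymin = ymin, ymax = ymax))
  v <- mesh$vertices
  sx <- w / diff(window$x); sz <- h / diff(window$z)
  px <- (v[, 1] - window$x[1]) * sx + 0.5       # pixel coords, col
  pz <- h - (v[, 3] - window$z[1]) * sz + 0.5   # row (top = 1)
  dep <- v[, 2]

  splat <- function(cols, rows, deps) {
    cc <- round(cols); rr <- round(rows)
    keep <- cc >= 1 & cc <= w & rr >= 1 & rr <= h
    if (!any(keep)) return(invisible())
    sub <- cbind(rr[keep], cc[keep])
    ymin[sub] <<- pmin(ymin[sub], deps[keep])
    ymax[sub] <<- pmax(ymax[sub], deps[keep])
    covered[sub] <<- TRUE
    invisible()
  }
  for (t in seq_len(nrow(f))) {
    i1 <- f[t, 1]; i2 <- f[t, 2]; i3 <- f[t, 3]
    x1 <- px[i1]; x2 <- px[i2]; x3 <- px[i3]
    z1 <- pz[i1]; z2 <- pz[i2]; z3 <- pz[i3]
    splat_edges <- function() {
      for (e in list(c(i1, i2), c(i2, i3), c(i3, i1))) {
        a <- e[1]; b <- e[2]
        ns <- max(2L, ceiling(max(abs(px[a] - px[b]),
                                  abs(pz[a] - pz[b]))) + 1L)
        tt <- seq(0, 1, length.out = ns)
        splat(px[a] + tt * (px[b] - px[a]), pz[a] + tt * (pz[b] - pz[a]),
              dep[a] + tt * (dep[b] - dep[a]))
      }
    }
    c0 <- max(1L, ceiling(min(x1, x2, x3) - 0.5))
    c1 <- min(w, floor(max(x1, x2, x3) + 0.5))
    r0 <- max(1L, ceiling(min(z1, z2, z3) - 0.5))
    r1 <- min(h, floor(max(z1, z2, z3) + 0.5))
    if (c0 > c1 || r0 > r1) { splat_edges(); next }
    det <- (x2 - x1) * (z3 - z1) - (x3 - x1) * (z2 - z1)
    if (abs(det) < 1e-12) { splat_edges(); next }
    cc <- c0:c1; rr <- r0:r1
    X <- matrix(cc, length(rr), length(cc), byrow = TRUE)
    Z <- matrix(rr, length(rr), length(cc))
    l2 <- ((X - x1) * (z3 - z1) - (x3 - x1) * (Z - z1)) / det
    l3 <- ((x2 - x1) * (Z - z1) - (X - x1) * (z2 - z1)) / det
    l1 <- 1 - l2 - l3
    tolb <- -1e-9
    inside <- l1 >= tolb & l2 >= tolb & l3 >= tolb
    if (!any(inside)) { splat_edges(); next }
    ydep <- l1 * dep[i1] + l2 * dep[i2] + l3 * dep[i3]
    sub <- cbind(Z[inside], X[inside])
    yin <- ydep[inside]
    ymin[sub] <- pmin(ymin[sub], yin)
    ymax[sub] <- pmax(ymax[sub], yin)
    covered[sub] <- TRUE
  }
  list(covered = covered, ymin = ymin, ymax = ymax)
}

#' @export
print.silhouette_video <- function(x, ...) {
  cat(sprintf("silhouette_video: %d frames at %d x %d px\n",
              dim(x$intensity)[3], x$resolution[1], x$resolution[2]))
  invisible(x)
}

#' Write / read silhouette videos as PNG frame directories
#'
#' Intensities are rescaled to the global maximum of the video when writing
#' (8-bit grayscale, `frame_0001.png` ...).
#'
#' @param video a `silhouette_video`.
#' @param dir directory for the PNG frames.
#' @export
write_png_frames <- function(video, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mx <- max(video$intensity)
  if (mx <= 0) mx <- 1
  for (fi in seq_len(dim(video$intensity)[3])) {
    png::writePNG(video$intensity[, , fi] / mx,
                  file.path(dir, sprintf("frame_%04d.png", fi)))
  }
  invisible(dir)
}

#' @rdname write_png_frames
#' @param mask_threshold intensity above which a pixel counts as liquid when
#'   reading frames back.
#' @export
read_png_frames <- function(dir, mask_threshold = 0) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG frames in ", dir)
  first <- png::readPNG(files[1])
  if (length(dim(first)) == 3) first <- rgb_to_gray(first)
  intensity <- array(0, dim = c(nrow(first), ncol(first), length(files)))
  for (i in seq_along(files)) {
    im <- png::readPNG(files[i])
    if (length(dim(im)) == 3) im <- rgb_to_gray(im)
    intensity[, , i] <- im
  }
  structure(list(intensity = intensity, mask = intensity > mask_threshold,
                 resolution = c(ncol(first), nrow(first)), window = NULL),
            class = "silhouette_video")
}

#' Grayscale conversion and image halving
#'
#' Standard luma conversion `0.2989 R + 0.5870 G + 0.1140 B` and 2x2 block
#' averaging (e.g. 800 x 600 frames halved to 400 x 300 before pixel-space
#' PCA).
#'
#' @param im height x width x 3 array in `[0, 1]`.
#' @export
rgb_to_gray <- function(im) {
  0.2989 * im[, , 1] + 0.5870 * im[, , 2] + 0.1140 * im[, , 3]
}

#' @rdname rgb_to_gray
#' @param m grayscale matrix with even dimensions.
#' @export
halve_image <- function(m) {
  h <- nrow(m); w <- ncol(m)
  if (h %% 2L || w %% 2L) stop("image dimensions must be even to halve")
  (m[seq(1, h, 2), seq(1, w, 2)] + m[seq(2, h, 2), seq(1, w, 2)] +
   m[seq(1, h, 2), seq(2, w, 2)] + m[seq(2, h, 2), seq(2, w, 2)]) / 4
}
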