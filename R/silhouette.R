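#' Frame filtering before silhouette measurement
#'
#' Contour measurements are unreliable when there is almost no liquid or
#' when regions are a single pixel wide, so each frame's binary mask is
#' cleaned by a morphological opening with a 2 x 2 structuring element
#' (which removes one-pixel-wide regions) and the frame is dropped when the
#' cleaned mask holds fewer than `min_pixels` liquid pixels (strict "fewer
#' than": a 300-pixel frame is retained at the default threshold).
#'
#' @param video a `silhouette_video` or logical h x w x frames array.
#' @param min_pixels minimum liquid pixel count.
#' @return list with `masks` (retained cleaned masks), `retained` (frame
#'   indices) and `unmeasurable` (`TRUE` when every frame was dropped).
#' @export
filter_frames <- function(video, min_pixels = 300L) {
  masks <- if (inherits(video, "silhouette_video")) video$mask else video
  kern <- matrix(1, 2, 2)
  keep <- list(); idx <- integer()
  for (f in seq_len(dim(masks)[3])) {
    m <- masks[, , f]
    opened <- EBImage::opening(m * 1, kern) > 0.5
    if (sum(opened) < min_pixels) next
    keep[[length(keep) + 1L]] <- opened
    idx <- c(idx, f)
  }
  list(masks = keep, retained = idx, unmeasurable = length(idx) == 0L)
}

## sub-pixel contours of a binary mask by marching squares at the half
## level; the padded mask is blurred twice (1-2-1 kernel) first, which
## suppresses the stair-step bias of binary contours (a digital disk's
## perimeter is then within ~0.5% of the true circle)
mask_contours <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask * 1
  pad <- blur121(blur121(pad))
  ## x along columns, y upward
  cl <- grDevices::contourLines(x = seq_len(w + 2L), y = seq_len(h + 2L),
                                z = t(pad)[, (h + 2L):1], levels = 0.5)
  cl
}

polygon_length <- function(x, y) {
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

## closed-contour resampling at fixed arc-length step, followed by a
## five-point moving average of the coordinates (stabilizes the finite-
## difference curvature against residual pixelation)
resample_contour <- function(x, y, step = 2) {
  x <- c(x, x[1]); y <- c(y, y[1])
  d <- sqrt(diff(x)^2 + diff(y)^2)
  keep <- c(TRUE, d > 1e-9)
  x <- x[keep]; y <- y[keep]
  d <- d[d > 1e-9]
  s <- c(0, cumsum(d))
  L <- s[length(s)]
  if (L < 4 * step) return(NULL)
  n_out <- max(8L, round(L / step))
  ss <- seq(0, L, length.out = n_out + 1L)[-(n_out + 1L)]
  p <- cbind(x = stats::approx(s, x, ss, ties = "ordered")$y,
             y = stats::approx(s, y, ss, ties = "ordered")$y)
  sm <- function(z) {
    zz <- stats::filter(c(z[(length(z) - 1):length(z)], z, z[1:2]),
                        rep(1 / 5, 5))
    as.numeric(zz[3:(length(z) + 2)])
  }
  cbind(x = sm(p[, 1]), y = sm(p[, 2]))
}

## signed curvature of a closed, arc-length-resampled contour by central
## finite differences
contour_curvature <- function(p) {
  n <- nrow(p)
  im <- c(n, seq_len(n - 1L)); ip <- c(seq_len(n)[-1], 1L)
  dx <- (p[ip, 1] - p[im, 1]) / 2; dy <- (p[ip, 2] - p[im, 2]) / 2
  ddx <- p[ip, 1] - 2 * p[, 1] + p[im, 1]
  ddy <- p[ip, 2] - 2 * p[, 2] + p[im, 2]
  den <- (dx^2 + dy^2)^1.5
  k <- (dx * ddy - dy * ddx) / pmax(den, 1e-12)
  k
}

#' Twenty silhouette shape statistics
#'
#' Simple 2D statistics of the liquid silhouette spanning shape, area,
#' curvature, spatial distribution and perimeter, computed per frame and
#' averaged over the retained frames. Perimeters and contour curvature are
#' measured on sub-pixel marching-squares contours; curvature on the outer
#' contour resampled at 2 px arc-length steps. The statistic list is held
#' in `silhouette_stat_names` and is swappable by computing a subset.
#'
#' @param masks list of binary masks from [filter_frames()], or a single
#'   mask matrix.
#' @return named numeric vector of 20 statistics (per-frame values averaged
#'   over frames).
#' @export
silhouette_statistics <- function(masks) {
  if (is.matrix(masks)) masks <- list(masks)
  if (length(masks) == 0L) stop("no retained frames to measure")
  per <- t(vapply(masks, frame_silhouette_stats,
                  numeric(length(silhouette_stat_names))))
  colMeans(per, na.rm = TRUE)
}

#' @rdname silhouette_statistics
#' @export
silhouette_stat_names <- c(
  "area", "perimeter", "circularity", "solidity", "convexity",
  "eccentricity", "elongation", "orientation", "extent", "component_count",
  "hole_count", "centroid_height", "vertical_extent", "horizontal_extent",
  "radial_spread", "centroid_dispersion", "mean_abs_contour_curvature",
  "contour_curvature_var", "curvature_zero_crossings",
  "perimeter_area_ratio")

frame_silhouette_stats <- function(mask) {
  h <- nrow(mask)
  A <- sum(mask)
  px <- which(mask, arr.ind = TRUE)
  xs <- px[, 2] - 0.5              # column -> x
  ys <- h - px[, 1] + 0.5          # row -> height from bottom
  cx <- mean(xs); cy <- mean(ys)
  mu20 <- mean((xs - cx)^2); mu02 <- mean((ys - cy)^2)
  mu11 <- mean((xs - cx) * (ys - cy))
  tr <- mu20 + mu02
  dd <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- tr / 2 + dd; l2 <- max(tr / 2 - dd, 1e-12)
  ecc <- sqrt(pmax(0, 1 - l2 / l1))
  elong <- sqrt(l1 / l2)
  orient <- 0.5 * atan2(2 * mu11, mu20 - mu02)

  cl <- mask_contours(mask)
  P <- sum(vapply(cl, function(c3) polygon_length(c3$x, c3$y), numeric(1)))
  circ <- 4 * pi * A / max(P, 1e-12)^2

  hull_i <- grDevices::chull(xs, ys)
  hx <- xs[hull_i]; hy <- ys[hull_i]
  ## pixel-center hull underestimates the rasterized region slightly; the
  ## ratio is still a good solidity measure
  hull_area <- max(polygon_area(hx, hy), A)
  hull_perim <- polygon_length(hx, hy)
  solidity <- A / hull_area
  convexity <- hull_perim / max(P, 1e-12)

  lab <- EBImage::bwlabel(mask * 1)
  ncomp <- max(lab)
  ## holes: background components not touching the border
  bg <- EBImage::bwlabel((1 - mask) * 1)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  nholes <- length(setdiff(unique(as.vector(bg)), c(0, border_labels)))

  bbox_a <- (diff(range(xs)) + 1) * (diff(range(ys)) + 1)
  radial <- sqrt(mean((xs - cx)^2 + (ys - cy)^2))
  if (ncomp > 1) {
    ccx <- tapply(xs, lab[px], mean); ccy <- tapply(ys, lab[px], mean)
    cdisp <- sqrt(mean((ccx - cx)^2 + (ccy - cy)^2))
  } else cdisp <- 0

  ## contour curvature on the longest (outer) contour
  lens <- vapply(cl, function(c3) polygon_length(c3$x, c3$y), numeric(1))
  outer <- cl[[which.max(lens)]]
  rp <- resample_contour(outer$x, outer$y, step = 2)
  if (is.null(rp)) {
    mac <- vac <- zc <- NA_real_
  } else {
    k <- contour_curvature(rp)
    mac <- mean(abs(k)); vac <- stats::var(k)
    sg <- sign(k); sg <- sg[sg != 0]
    zc <- sum(diff(sg) != 0)
  }

  c(area = A, perimeter = P, circularity = circ, solidity = solidity,
    convexity = convexity, eccentricity = ecc, elongation = elong,
    orientation = orient, extent = A / bbox_a, component_count = ncomp,
    hole_count = nholes, centroid_height = cy,
    vertical_extent = diff(range(ys)) + 1,
    horizontal_extent = diff(range(xs)) + 1,
    radial_spread = radial, centroid_dispersion = cdisp,
    mean_abs_contour_curvature = mac, contour_curvature_var = vac,
    curvature_zero_crossings = zc, perimeter_area_ratio = P / max(A, 1))
}

#' Single-predictor silhouette model
#'
#' Min-max normalizes each statistic across the stimulus set, aligns each
#' statistic's sign so that it correlates positively with the training
#' viscosity labels (the original statistic set was constructed to covary
#' positively with viscosity; an arbitrary set must be calibrated), and
#' takes the arithmetic mean of the normalized statistics as the single
#' predictor per stimulus.
#'
#' @param stats stimuli x statistics matrix of raw statistics.
#' @param train_labels viscosity labels used only for sign alignment; when
#'   `NULL` no alignment is applied.
#' @return numeric predictor per stimulus, with the per-statistic signs as
#'   an attribute.
#' @export
stats_mean_predictor <- function(stats, train_labels = NULL) {
  stats <- as.matrix(stats)
  ok <- apply(stats, 2, function(col) all(is.finite(col)))
  stats <- stats[, ok, drop = FALSE]
  signs <- rep(1, ncol(stats))
  if (!is.null(train_labels)) {
    r <- suppressWarnings(apply(stats, 2, stats::cor, y = train_labels))
    signs <- ifelse(is.na(r) | r >= 0, 1, -1)
  }
  norm <- apply(sweep(stats, 2, signs, `*`), 2, minmax_norm)
  structure(rowMeans(norm), signs = stats::setNames(signs, colnames(stats)))
}
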