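## ---- small image helpers (matrices indexed [row, col]) ---------------------

## separable 1-2-1 blur with replicated borders
blur121 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up <- m[c(1, seq_len(h - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(h)[-1], h), , drop = FALSE]
  m2 <- (up + 2 * m + dn) / 4
  lf <- m2[, c(1, seq_len(w - 1L)), drop = FALSE]
  rt <- m2[, c(seq_len(w)[-1], w), drop = FALSE]
  (lf + 2 * m2 + rt) / 4
}

pyr_down <- function(m) {
  b <- blur121(m)
  b[seq(1, nrow(b), 2), seq(1, ncol(b), 2), drop = FALSE]
}

## bilinear sampling at fractional (row, col) positions; border replicated
bilinear_sample <- function(m, rows, cols) {
  h <- nrow(m); w <- ncol(m)
  rows <- pmin(pmax(rows, 1), h); cols <- pmin(pmax(cols, 1), w)
  r0 <- floor(rows); c0 <- floor(cols)
  r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
  fr <- rows - r0; fc <- cols - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) + m[cbind(r1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c1)] * (1 - fr) * fc + m[cbind(r1, c1)] * fr * fc
}

resize_bilinear <- function(m, h2, w2) {
  rows <- matrix(seq(1, nrow(m), length.out = h2), h2, w2)
  cols <- matrix(seq(1, ncol(m), length.out = w2), h2, w2, byrow = TRUE)
  matrix(bilinear_sample(m, as.vector(rows), as.vector(cols)), h2, w2)
}

## fast box sum of half-width r via integral image
box_sum <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  cs <- apply(rbind(0, m), 2, cumsum)
  lo <- pmax(seq_len(h) - r, 0L) + 1L
  hi <- pmin(seq_len(h) + r, h) + 1L
  v <- cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
  cs2 <- t(apply(cbind(0, v), 1, cumsum))
  lo <- pmax(seq_len(w) - r, 0L) + 1L
  hi <- pmin(seq_len(w) + r, w) + 1L
  cs2[, hi, drop = FALSE] - cs2[, lo, drop = FALSE]
}

grad_x <- function(m) {  # along columns
  w <- ncol(m)
  (m[, c(seq_len(w)[-1], w), drop = FALSE] -
     m[, c(1, seq_len(w - 1L)), drop = FALSE]) / 2
}
grad_y <- function(m) {  # along rows
  h <- nrow(m)
  (m[c(seq_len(h)[-1], h), , drop = FALSE] -
     m[c(1, seq_len(h - 1L)), , drop = FALSE]) / 2
}

## dense iterated pyramidal Lucas-Kanade flow from im1 to im2;
## returns u (col displacement) and v (row displacement) matrices
lk_flow <- function(im1, im2, pyramid_levels = 3L, iterations = 3L,
                    window = 3L, eps = 1e-4) {
  p1 <- list(im1); p2 <- list(im2)
  for (l in seq_len(pyramid_levels - 1L)) {
    if (min(dim(p1[[l]])) < 8L) break
    p1[[l + 1L]] <- pyr_down(p1[[l]])
    p2[[l + 1L]] <- pyr_down(p2[[l]])
  }
  nl <- length(p1)
  u <- matrix(0, nrow(p1[[nl]]), ncol(p1[[nl]]))
  v <- matrix(0, nrow(p1[[nl]]), ncol(p1[[nl]]))
  for (l in rev(seq_len(nl))) {
    A <- p1[[l]]; B <- p2[[l]]
    h <- nrow(A); w <- ncol(A)
    if (nrow(u) != h || ncol(u) != w) {
      u <- resize_bilinear(u, h, w) * 2
      v <- resize_bilinear(v, h, w) * 2
    }
    Ix <- grad_x(A); Iy <- grad_y(A)
    Sxx <- box_sum(Ix * Ix, window); Syy <- box_sum(Iy * Iy, window)
    Sxy <- box_sum(Ix * Iy, window)
    rows0 <- matrix(seq_len(h), h, w); cols0 <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (it in seq_len(iterations)) {
      warped <- matrix(bilinear_sample(B, as.vector(rows0 + v),
                                       as.vector(cols0 + u)), h, w)
      It <- warped - A
      Sxt <- box_sum(Ix * It, window); Syt <- box_sum(Iy * It, window)
      det <- (Sxx + eps) * (Syy + eps) - Sxy^2
      du <- (-(Syy + eps) * Sxt + Sxy * Syt) / det
      dv <- (Sxy * Sxt - (Sxx + eps) * Syt) / det
      du[!is.finite(du)] <- 0; dv[!is.finite(dv)] <- 0
      u <- u + du; v <- v + dv
    }
  }
  list(u = u, v = v)
}

#' Mean optical-flow speed of a silhouette video
#'
#' Dense optical flow between consecutive frames by the coarse-to-fine
#' iterated pyramidal Lucas-Kanade method; the statistic is the mean flow
#' magnitude (px/frame) over liquid-mask pixels (or the whole frame with
#' `mask_only = FALSE`), averaged over frame pairs. Static videos yield 0;
#' frame pairs with an empty mask are skipped and flagged.
#'
#' @param video a `silhouette_video`, or an h x w x frames intensity array.
#' @param pyramid_levels number of pyramid levels.
#' @param iterations Lucas-Kanade update iterations per level.
#' @param window box-window half-width for the structure sums (px).
#' @param mask_only average the magnitude over liquid pixels only.
#' @return mean speed in px/frame, with per-pair speeds and the count of
#'   skipped (empty-mask) pairs as attributes.
#' @export
mean_flow_speed <- function(video, pyramid_levels = 3L, iterations = 3L,
                            window = 3L, mask_only = TRUE) {
  if (inherits(video, "silhouette_video")) {
    ims <- video$intensity; masks <- video$mask
  } else {
    ims <- video; masks <- NULL
  }
  nf <- dim(ims)[3]
  if (nf < 2L) stop("need at least 2 frames")
  mx <- max(ims); if (mx <= 0) mx <- 1
  speeds <- rep(NA_real_, nf - 1L)
  skipped <- 0L
  for (f in seq_len(nf - 1L)) {
    fl <- lk_flow(ims[, , f] / mx, ims[, , f + 1L] / mx,
                  pyramid_levels, iterations, window)
    mag <- sqrt(fl$u^2 + fl$v^2)
    if (mask_only && !is.null(masks)) {
      m <- masks[, , f]
      if (!any(m)) { skipped <- skipped + 1L; next }
      speeds[f] <- mean(mag[m])
    } else {
      speeds[f] <- mean(mag)
    }
  }
  structure(mean(speeds, na.rm = TRUE), per_pair = speeds,
            skipped_pairs = skipped)
}
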