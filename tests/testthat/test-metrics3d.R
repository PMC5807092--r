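flat_square <- function(n = 25) {
  xs <- seq(0, 1, length.out = n)
  v <- cbind(rep(xs, n), rep(xs, each = n), 0)
  idx <- function(i, j) (j - 1L) * n + i
  i <- rep(seq_len(n - 1), n - 1); j <- rep(seq_len(n - 1), each = n - 1)
  mesh_frame(v, rbind(cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                      cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))))
}

test_that("angular-curvature metric is 1 on the unit sphere and 0 on a plane", {
  expect_equal(metric_angular_curvature(sphere4_field()), 1, tolerance = 0.05)
  fsq <- principal_curvatures(flat_square())
  expect_equal(metric_angular_curvature(fsq), 0, tolerance = 1e-6)
})

test_that("angular-curvature metric halves when the sphere doubles", {
  f1 <- sphere4_field()
  f2 <- principal_curvatures(icosphere(4, radius = 2))
  expect_equal(metric_angular_curvature(f2),
               metric_angular_curvature(f1) / 2, tolerance = 0.01)
})

test_that("flatness metric integrates |n.z| over the surface", {
  expect_equal(metric_flatness(flat_square()), 1, tolerance = 1e-10)
  ## vertical patch: normals horizontal
  vert <- flat_square()
  vert$vertices <- vert$vertices[, c(1, 3, 2)]
  expect_equal(metric_flatness(vert), 0, tolerance = 1e-10)
  expect_equal(metric_flatness(sphere4()), 2 * pi, tolerance = 0.05)
})

test_that("center-of-mass height is exact on closed solids", {
  expect_equal(as.numeric(metric_com_height(icosphere(3, center = c(0, 0, 3)))),
               3, tolerance = 1e-6)
  expect_equal(as.numeric(metric_com_height(box_mesh())), 0.5)
  expect_equal(as.numeric(metric_com_height(cone_mesh(h = 2))), 0.5,
               tolerance = 1e-3)
  expect_true(attr(metric_com_height(box_mesh()), "watertight"))
  ## open meshes fall back to the flagged surface centroid
  open_m <- metric_com_height(flat_square())
  expect_false(attr(open_m, "watertight"))
  expect_equal(as.numeric(open_m), 0)
})

test_that("total absolute curvature is 4 pi on spheres and 8 pi on the torus", {
  expect_equal(metric_total_abs_curvature(sphere4_field()), 4 * pi,
               tolerance = 0.05)
  f2 <- principal_curvatures(icosphere(3, radius = 3))
  expect_equal(metric_total_abs_curvature(f2), 4 * pi, tolerance = 0.05)
  ft <- principal_curvatures(torus_mesh(R = 2, r = 0.5))
  expect_equal(metric_total_abs_curvature(ft), 8 * pi, tolerance = 0.05)
  fsq <- principal_curvatures(flat_square())
  expect_equal(metric_total_abs_curvature(fsq), 0, tolerance = 1e-6)
})

test_that("metrics obey scaling covariance and rigid-motion invariance", {
  m1 <- icosphere(3)
  s <- 2
  m2 <- icosphere(3, radius = s)
  f1 <- principal_curvatures(m1); f2 <- principal_curvatures(m2)
  expect_equal(metric_angular_curvature(f2),
               metric_angular_curvature(f1) / s, tolerance = 0.01)
  expect_equal(metric_flatness(m2, f2), s^2 * metric_flatness(m1, f1),
               tolerance = 0.01)
  expect_equal(metric_total_abs_curvature(f2),
               metric_total_abs_curvature(f1), tolerance = 0.01)
  ## rotation about an arbitrary axis
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mr <- m1; mr$vertices <- m1$vertices %*% t(R)
  fr <- principal_curvatures(mr)
  expect_equal(metric_angular_curvature(fr), metric_angular_curvature(f1),
               tolerance = 0.01)
  expect_equal(metric_total_abs_curvature(fr),
               metric_total_abs_curvature(f1), tolerance = 0.01)
  expect_equal(metric_flatness(mr, fr), metric_flatness(m1, f1),
               tolerance = 0.01)
  ## translation covariance of the centroid height
  mt <- m1; mt$vertices[, 3] <- mt$vertices[, 3] + 5
  expect_equal(as.numeric(metric_com_height(mt)),
               as.numeric(metric_com_height(m1)) + 5, tolerance = 1e-6)
})

test_that("extract_metrics aggregates and z-normalizes across stimuli", {
  ## per-frame metric matrices injected directly: constant per frame
  mk <- function(vals) matrix(rep(vals, each = 12), nrow = 12,
                              dimnames = list(NULL, c("m1", "m2", "m3", "m4")))
  out <- extract_metrics(list(mk(c(1, 2, 1, 4)), mk(c(3, 2.5, 3, 8))),
                         aggregation = "full_sequence")
  expect_equal(out$m3_com_height, c(1, 3))
  ## two-point z-scores (sample sd): {1,3} -> -1/sqrt(2), +1/sqrt(2)
  expect_equal(out$m3_com_height_z, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(out$m1_angular_curvature_z, c(-0.707, 0.707), tolerance = 1e-3)
})

test_that("duplicated stimuli make z-normalization fail loudly", {
  mk <- matrix(1:48, nrow = 12)
  expect_error(extract_metrics(list(mk, mk), aggregation = "full_sequence"),
               "zero variance")
  expect_error(extract_metrics(list(mk), aggregation = "full_sequence"),
               "at least 2")
})

test_that("per-period aggregation uses within-period medians scaled by the
           across-period median", {
  set.seed(1)
  pm <- matrix(stats::runif(6 * 4 * 5, 1, 2), nrow = 30)
  pm2 <- pm * 1.7 + 0.2
  out <- extract_metrics(list(pm, pm2), aggregation = "per_time_period",
                         n_periods = 6)
  expect_equal(nrow(out), 12)
  expect_equal(unique(out$time_period), 1:6)
  ## manual check for stimulus 1, metric 1
  med <- tapply(pm[, 1], rep(1:6, each = 5), stats::median)
  expect_equal(out$m1_angular_curvature[out$stimulus_id == 1],
               as.numeric(med / stats::median(med)))
})
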