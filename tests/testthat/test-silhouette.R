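test_that("frame filter applies the strict 300-pixel rule after opening", {
  arr <- array(FALSE, c(100, 100, 4))
  arr[20:33, 30:50, 1] <- TRUE     # 14 x 21 = 294 px -> dropped
  arr[20:34, 30:49, 2] <- TRUE     # 15 x 20 = 300 px -> retained
  arr[10, 1:99, 3] <- TRUE         # 1-px line, 99 px: removed by opening
  arr[20:40, 20:40, 4] <- TRUE     # 441 px -> retained
  fr <- filter_frames(arr)
  expect_equal(fr$retained, c(2L, 4L))
  expect_false(fr$unmeasurable)
  ## a long 1-px-wide region above threshold is still removed by opening
  ln <- array(FALSE, c(100, 100, 1)); ln[50, 1:99, 1] <- TRUE
  ln[50, 1:99, 1] <- TRUE
  fr2 <- filter_frames(ln)
  expect_true(fr2$unmeasurable)
  expect_length(fr2$retained, 0)
})

test_that("opening removes 1-px appendages but keeps 2-px bodies", {
  m <- array(FALSE, c(60, 60, 1))
  m[20:40, 20:40, 1] <- TRUE
  m[30, 41:55, 1] <- TRUE          # 1-px tail
  fr <- filter_frames(m, min_pixels = 100)
  expect_equal(sum(fr$masks[[1]]), 21 * 21)
})

test_that("silhouette statistics are accurate on a disk", {
  st <- silhouette_statistics(disk_mask(200, 50))
  expect_equal(unname(st["area"]), pi * 50^2, tolerance = 0.01)
  expect_equal(unname(st["perimeter"]), 2 * pi * 50, tolerance = 0.02)
  expect_equal(unname(st["circularity"]), 1, tolerance = 0.05)
  expect_equal(unname(st["mean_abs_contour_curvature"]), 1 / 50,
               tolerance = 0.05)
  expect_equal(unname(st["solidity"]), 1, tolerance = 0.02)
  expect_equal(unname(st["component_count"]), 1)
  expect_equal(unname(st["hole_count"]), 0)
  expect_equal(unname(st["eccentricity"]), 0, tolerance = 0.05)
})

test_that("silhouette statistics are accurate on a rectangle", {
  st <- silhouette_statistics(rect_mask())  # 50 x 100
  expect_equal(unname(st["area"]), 5000)
  expect_equal(unname(st["elongation"]), 2, tolerance = 0.01)
  expect_equal(unname(st["extent"]), 1, tolerance = 0.01)
  expect_equal(unname(st["perimeter"]), 300, tolerance = 0.05)
  expect_equal(unname(st["vertical_extent"]), 50)
  expect_equal(unname(st["horizontal_extent"]), 100)
})

test_that("component count and holes are detected", {
  m <- disk_mask(200, 20, cx = 60, cy = 60) | disk_mask(200, 20, cx = 140, cy = 140)
  st <- silhouette_statistics(m)
  expect_equal(unname(st["component_count"]), 2)
  expect_gt(unname(st["centroid_dispersion"]), 0)
  ## annulus: one hole
  ann <- disk_mask(200, 50) & !disk_mask(200, 20)
  expect_equal(unname(silhouette_statistics(ann)["hole_count"]), 1)
})

test_that("silhouette statistics are translation invariant", {
  a <- silhouette_statistics(disk_mask(300, 40, cx = 80, cy = 90))
  b <- silhouette_statistics(disk_mask(300, 40, cx = 190, cy = 170))
  drop <- c("centroid_height")   # position statistics move with the shape
  expect_equal(a[setdiff(names(a), drop)], b[setdiff(names(b), drop)],
               tolerance = 1e-6)
})

test_that("the mean predictor reduces to a single aligned column", {
  ## identical statistics across columns: predictor equals that column
  x <- stats::runif(10)
  stats_m <- matrix(x, 10, 5)
  p <- stats_mean_predictor(stats_m)
  expect_equal(as.numeric(p), (x - min(x)) / diff(range(x)))
  ## one stimulus maximal on every statistic scores exactly 1
  stats_m2 <- rbind(matrix(stats::runif(45), 9, 5), 2)
  expect_equal(max(stats_mean_predictor(stats_m2)), 1)
  expect_equal(which.max(stats_mean_predictor(stats_m2)), 10L)
})

test_that("monotone statistics give a predictor that rank-orders viscosity", {
  v <- viscosity_grid(8, 0.01, 10)
  stats_m <- cbind(log10(v), 3 * log10(v) + 2, -log10(v), sqrt(seq_along(v)))
  p <- stats_mean_predictor(stats_m, train_labels = v)
  expect_equal(order(p), order(v))
  ## sign alignment flipped the negatively covarying column
  expect_equal(unname(attr(p, "signs")[3]), -1)
})
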