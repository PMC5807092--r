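scene_small <- function(...) scene_config("test", grid_n = 32L, ...)

test_that("simulator is deterministic in (parameters, seed)", {
  sc <- scene_small(perturbation = list(kind = "noise", amplitude = 0.05))
  a <- generate_liquid_sequence(sc, 0.1, n_frames = 20, seed = 7)
  b <- generate_liquid_sequence(sc, 0.1, n_frames = 20, seed = 7)
  expect_identical(a$heights, b$heights)
  expect_identical(a$frames[[20]]$vertices, b$frames[[20]]$vertices)
  c3 <- generate_liquid_sequence(sc, 0.1, n_frames = 20, seed = 8)
  expect_false(identical(a$heights, c3$heights))
})

test_that("poured volume is conserved at every frame", {
  sc <- scene_small()
  s <- generate_liquid_sequence(sc, 0.05, n_frames = 60, seed = 1)
  vols <- vapply(seq_len(60), function(f) frame_volume(s, f), numeric(1))
  expect_equal(vols, s$volume_in, tolerance = 0.01)
  ## with obstacles the walls are no-flux too
  obst <- matrix(FALSE, 32, 32); obst[20, 5:28] <- TRUE
  so <- generate_liquid_sequence(scene_small(obstacle_map = obst), 0.01,
                                 n_frames = 40, seed = 2)
  expect_equal(frame_volume(so, 40), so$volume_in[40], tolerance = 0.01)
})

test_that("footprint area is non-increasing in viscosity", {
  sc <- scene_small()
  grid7 <- viscosity_grid(7, 0.004, 7.74)
  fp <- vapply(grid7, function(v) {
    s <- generate_liquid_sequence(sc, v, n_frames = 150, seed = 3)
    footprint_area(s, 150)
  }, numeric(1))
  expect_true(all(diff(fp) <= 0))
  expect_lt(fp[7], fp[1])
})

test_that("pouring onto an obstacle is a configuration error", {
  obst <- matrix(FALSE, 32, 32); obst[16, 16] <- TRUE
  sc <- scene_config("bad", pour_location = c(0.5, 0.5),
                     obstacle_map = obst, grid_n = 32L)
  expect_error(generate_liquid_sequence(sc, 0.1, 5, 1), "obstacle")
})

test_that("viscosity outside the physical range is rejected", {
  sc <- scene_small()
  expect_error(generate_liquid_sequence(sc, 0.0001, 5, 1), "viscosity")
  expect_error(generate_liquid_sequence(sc, 150, 5, 1), "viscosity")
})

test_that("full stimuli default to 300 frames at 30 fps", {
  f <- formals(generate_liquid_sequence)
  expect_equal(eval(f$n_frames), 300L)
  expect_equal(eval(f$fps), 30)
})

test_that("mesh frames are valid triangulations of the height field", {
  sc <- scene_small()
  s <- generate_liquid_sequence(sc, 1, n_frames = 5, seed = 1)
  m <- s$frames[[5]]
  expect_true(all(m$faces >= 1) && all(m$faces <= nrow(m$vertices)))
  expect_equal(m$up_axis, "+z")
  ## heights round-trip into vertex z
  expect_equal(sort(unique(m$vertices[, 3])),
               sort(unique(as.vector(s$heights[, , 5]))))
})

test_that("OBJ round trip preserves the mesh", {
  sc <- scene_small()
  s <- generate_liquid_sequence(sc, 1, n_frames = 2, seed = 1)
  tmp <- withr::local_tempfile(fileext = ".obj")
  write_obj(s$frames[[2]], tmp)
  back <- read_obj(tmp)
  expect_equal(back$vertices, s$frames[[2]]$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$faces, s$frames[[2]]$faces, ignore_attr = TRUE)
})
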