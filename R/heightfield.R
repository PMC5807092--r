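#' Scene configuration for the liquid simulator
#'
#' Describes one pouring scene: where the liquid enters the square domain,
#' how fast it is poured, optional solid obstacles (no-flux cells), and an
#' optional perturbation of the pour point that makes scenes dynamically
#' distinct (a circular stirring orbit or random jitter). Scenes emulate
#' between-scene variation — different containers, holes, stirrers — not the
#' visual realism of any particular setup.
#'
#' @param scene_id character label.
#' @param pour_location length-2 numeric, pour point in meters.
#' @param obstacle_map logical matrix (`TRUE` = solid cell) matching
#'   `grid_n`, or `NULL` for an open domain.
#' @param source_rate poured volume in m^3/s (> 0).
#' @param perturbation list with `kind` one of `"none"`, `"stir"`, `"noise"`
#'   and `amplitude` in meters.
#' @param domain_size side length of the square domain in meters.
#' @param grid_n number of simulation cells per side.
#' @return a `scene_config` list.
#' @export
scene_config <- function(scene_id, pour_location = c(0.5, 0.5),
                         obstacle_map = NULL, source_rate = 8e-3,
                         perturbation = list(kind = "none", amplitude = 0),
                         domain_size = 1, grid_n = 48L) {
  stopifnot(length(pour_location) == 2L, is.numeric(pour_location))
  if (source_rate <= 0) stop("source_rate must be positive")
  if (domain_size <= 0) stop("domain_size must be positive")
  if (!perturbation$kind %in% c("none", "stir", "noise"))
    stop("perturbation kind must be none, stir or noise")
  if (!is.null(obstacle_map)) {
    obstacle_map <- as.matrix(obstacle_map)
    if (!all(dim(obstacle_map) == grid_n))
      stop("obstacle_map must be a grid_n x grid_n logical matrix")
    mode(obstacle_map) <- "logical"
  }
  structure(list(scene_id = as.character(scene_id),
                 pour_location = as.numeric(pour_location),
                 obstacle_map = obstacle_map,
                 source_rate = source_rate,
                 perturbation = perturbation,
                 domain_size = domain_size,
                 grid_n = as.integer(grid_n)),
            class = "scene_config")
}

#' Default scene set
#'
#' A family of eight qualitatively different scenes (central pour, corner
#' pour, stirred, jittered source, walls with gaps, pillar fields) used as
#' the multi-context stimulus set, plus the canonical `"pouring"` scene used
#' for training. All share the same domain and source rate so viscosity is
#' the only systematically varied physical parameter.
#'
#' @param grid_n simulation resolution per side.
#' @return named list of [scene_config()] objects.
#' @export
default_scenes <- function(grid_n = 48L) {
  wall_with_gap <- function(n, row_frac, gap) {
    m <- matrix(FALSE, n, n)
    r <- max(2L, round(row_frac * n))
    m[r, ] <- TRUE
    keep <- seq(round(n * (0.5 - gap / 2)), round(n * (0.5 + gap / 2)))
    m[r, keep] <- FALSE
    m
  }
  pillars <- function(n, pitch) {
    m <- matrix(FALSE, n, n)
    ij <- seq(round(n / 4), round(3 * n / 4), by = pitch)
    m[ij, ij] <- TRUE
    m
  }
  scenes <- list(
    pouring  = scene_config("pouring", c(0.5, 0.5), grid_n = grid_n),
    corner   = scene_config("corner", c(0.25, 0.25), grid_n = grid_n),
    stirred  = scene_config("stirred", c(0.5, 0.5), grid_n = grid_n,
                            perturbation = list(kind = "stir", amplitude = 0.18)),
    jittered = scene_config("jittered", c(0.5, 0.5), grid_n = grid_n,
                            perturbation = list(kind = "noise", amplitude = 0.08)),
    gap_low  = scene_config("gap_low", c(0.5, 0.7), grid_n = grid_n,
                            obstacle_map = wall_with_gap(grid_n, 0.45, 0.15)),
    gap_wide = scene_config("gap_wide", c(0.75, 0.5), grid_n = grid_n,
                            obstacle_map = wall_with_gap(grid_n, 0.5, 0.4)),
    pillars  = scene_config("pillars", c(0.4, 0.4), grid_n = grid_n,
                            obstacle_map = pillars(grid_n, 6L)),
    offset_stir = scene_config("offset_stir", c(0.35, 0.6), grid_n = grid_n,
                               perturbation = list(kind = "stir", amplitude = 0.1))
  )
  scenes
}

## Five-point no-flux Laplacian step: flux only between pairs of open cells,
## so poured volume is conserved exactly (obstacles and the outer boundary
## are walls).
diffuse_step <- function(h, alpha, open) {
  n <- nrow(h)
  flux <- matrix(0, n, n)
  ## x-direction neighbor pairs
  dh <- h[-1, , drop = FALSE] - h[-n, , drop = FALSE]
  ok <- open[-1, , drop = FALSE] & open[-n, , drop = FALSE]
  dh[!ok] <- 0
  flux[-n, ] <- flux[-n, ] + dh
  flux[-1, ] <- flux[-1, ] - dh
  ## y-direction
  dh <- h[, -1, drop = FALSE] - h[, -n, drop = FALSE]
  ok <- open[, -1, drop = FALSE] & open[, -n, drop = FALSE]
  dh[!ok] <- 0
  flux[, -n] <- flux[, -n] + dh
  flux[, -1] <- flux[, -1] - dh
  h + alpha * flux
}

#' Simulate a liquid pouring sequence
#'
#' A 2.5-D height-field model of viscous spreading: poured volume enters at
#' the (possibly perturbed) pour point and relaxes by lateral diffusion with
#' coefficient `D = spread_coef / viscosity`, so runny liquids flatten out
#' quickly while viscous ones pile up. Obstacle cells and the domain
#' boundary are no-flux walls, making the simulator exactly volume
#' conserving. Each frame's surface is triangulated into a regular-grid
#' mesh. The model deliberately trades fluid realism for a controllable,
#' deterministic, viscosity-monotone family of shapes.
#'
#' @param scene a [scene_config()].
#' @param viscosity dynamic viscosity in Pa s, within `[0.001, 100]`.
#' @param n_frames number of frames (full stimuli use 300 at 30 fps, i.e.
#'   10 s).
#' @param seed integer seed; the sequence is a pure function of
#'   `(scene, viscosity, n_frames, seed)`.
#' @param fps frames per second.
#' @param spread_coef spreading constant `c` in `D = c / viscosity`
#'   (m^2 s^-1 Pa s); the default makes the runniest liquid wet roughly 80%
#'   of the domain within 10 s.
#' @return a `mesh_sequence`: list with `frames` (each a `mesh_frame`),
#'   `heights` (grid_n x grid_n x n_frames array, meters), `fps`,
#'   `viscosity`, `scene`, `seed`, and `volume_in` (cumulative poured volume
#'   per frame, m^3).
#' @export
generate_liquid_sequence <- function(scene, viscosity, n_frames = 300L,
                                     seed = 1L, fps = 30, spread_coef = 8e-7) {
  stopifnot(inherits(scene, "scene_config"))
  if (viscosity < 0.001 || viscosity > 100)
    stop("viscosity must lie in [0.001, 100] Pa s")
  n <- scene$grid_n
  dx <- scene$domain_size / n
  dt <- 1 / fps
  open <- if (is.null(scene$obstacle_map)) matrix(TRUE, n, n) else !scene$obstacle_map

  cell_of <- function(p) pmin(n, pmax(1L, as.integer(ceiling(p / dx))))
  pc <- cell_of(scene$pour_location)
  if (!open[pc[1], pc[2]])
    stop("pour_location falls on an obstacle cell")

  D <- spread_coef / viscosity
  alpha_tot <- D * dt / dx^2
  nsub <- max(1L, ceiling(alpha_tot / 0.2))
  alpha <- alpha_tot / nsub

  ## deposition kernel: small Gaussian bump over open cells
  ker_r <- 2L
  off <- seq(-ker_r, ker_r)
  kw <- outer(off, off, function(i, j) exp(-(i^2 + j^2) / 2))

  h <- matrix(0, n, n)
  heights <- array(0, dim = c(n, n, n_frames))
  volume_in <- numeric(n_frames)
  cell_area <- dx^2
  poured <- 0

  rng <- with_seed(seed, matrix(stats::rnorm(2L * n_frames), ncol = 2L))

  for (f in seq_len(n_frames)) {
    t <- (f - 1) * dt
    p <- scene$pour_location
    amp <- scene$perturbation$amplitude
    if (scene$perturbation$kind == "stir") {
      p <- p + amp * c(cos(2 * pi * 0.5 * t), sin(2 * pi * 0.5 * t))
    } else if (scene$perturbation$kind == "noise") {
      p <- p + amp * rng[f, ]
    }
    p <- pmin(scene$domain_size - dx / 2, pmax(dx / 2, p))
    pc <- cell_of(p)
    ii <- pc[1] + off; jj <- pc[2] + off
    keep_i <- ii >= 1 & ii <= n; keep_j <- jj >= 1 & jj <= n
    kk <- kw[keep_i, keep_j, drop = FALSE]
    om <- open[ii[keep_i], jj[keep_j], drop = FALSE]
    kk[!om] <- 0
    if (sum(kk) > 0) {
      dv <- scene$source_rate * dt           # m^3 this frame
      h[ii[keep_i], jj[keep_j]] <- h[ii[keep_i], jj[keep_j]] +
        (kk / sum(kk)) * dv / cell_area
      poured <- poured + dv
    }
    for (s in seq_len(nsub)) h <- diffuse_step(h, alpha, open)
    heights[, , f] <- h
    volume_in[f] <- poured
  }

  frames <- lapply(seq_len(n_frames), function(f)
    heightfield_mesh(heights[, , f], dx))
  structure(list(frames = frames, heights = heights, fps = fps,
                 viscosity = viscosity, scene = scene, seed = seed,
                 volume_in = volume_in, cell_area = cell_area),
            class = "mesh_sequence")
}

#' @export
print.mesh_sequence <- function(x, ...) {
  cat(sprintf("mesh_sequence: %d frames @ %g fps, viscosity %g Pa s, scene '%s'\n",
              length(x$frames), x$fps, x$viscosity, x$scene$scene_id))
  invisible(x)
}

#' Liquid footprint area of a frame
#'
#' Area (m^2) of cells whose film thickness exceeds `eps`; the basic
#' spread-rate statistic, monotonically decreasing in viscosity.
#'
#' @param seq a `mesh_sequence`.
#' @param frame frame index.
#' @param eps thickness threshold in meters.
#' @export
footprint_area <- function(seq, frame, eps = 1e-5) {
  sum(seq$heights[, , frame] > eps) * seq$cell_area
}

#' Liquid volume held in a frame
#'
#' Integrated height times cell area (m^3); equals the cumulative poured
#' volume because walls are no-flux.
#' @param seq a `mesh_sequence`.
#' @param frame frame index.
#' @export
frame_volume <- function(seq, frame) {
  sum(seq$heights[, , frame]) * seq$cell_area
}
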