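# Shared fixtures, built in code and memoised across test files (the
# subdivision-4 icosphere curvature field is the expensive one).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

sphere4 <- function() fixture("sphere4", function() icosphere(4))
sphere4_field <- function() fixture("sphere4_field", function()
  principal_curvatures(sphere4()))

disk_mask <- function(n = 200, r = 50, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n), n, n)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

rect_mask <- function(n = 200, rows = 50:99, cols = 40:139) {
  m <- matrix(FALSE, n, n)
  m[rows, cols] <- TRUE
  m
}

## sparse smooth random texture for the optical-flow oracle
textured_image <- function(h = 120, w = 160, n_blobs = 40, seed = 3) {
  set.seed(seed)
  m <- matrix(0, h, w)
  for (i in seq_len(n_blobs)) {
    r <- sample(10:(h - 10), 1); c3 <- sample(10:(w - 10), 1)
    m[r + (-2:2), c3 + (-2:2)] <- m[r + (-2:2), c3 + (-2:2)] +
      matrix(stats::runif(25), 5)
  }
  ## soften edges so gradients are informative
  for (k in 1:2) {
    m <- (m[c(1, seq_len(h - 1)), ] + 2 * m + m[c(2:h, h), ]) / 4
    m <- (m[, c(1, seq_len(w - 1))] + 2 * m + m[, c(2:w, w)]) / 4
  }
  m
}

shift_image <- function(m, dr = 0, dc = 0) {
  out <- matrix(0, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m) - dr); src_c <- seq_len(ncol(m) - dc)
  out[src_r + dr, src_c + dc] <- m[src_r, src_c]
  out
}

## ground truth with externally supplied iid factor scores (for recovery
## simulations that do not want the viscosity-driven structure)
iid_ground_truth <- function(n, loadings, noise_sd, seed) {
  design <- data.frame(viscosity = 10^seq(-3, 2, length.out = n),
                       scene_id = "sim", time_period = "full")
  tr <- make_ground_truth(design, loadings = loadings, noise_sd = noise_sd,
                          seed = seed)
  set.seed(seed)
  tr$factor_scores <- matrix(stats::rnorm(n * ncol(loadings)),
                             ncol = ncol(loadings))
  tr
}

small_truth <- function(seed = 1, design = set2_design(), ...) {
  make_ground_truth(design, seed = seed, ...)
}
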