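#' Study run configuration
#'
#' One list holding every knob of the end-to-end reproduction: the designs
#' (viscosity grids, scenes, time periods, repetitions), generator
#' parameters, model flags and the master seed from which every component
#' seed is derived. All outputs are a pure function of the configuration.
#'
#' @param seed master integer seed.
#' @param repetitions rating repetitions per stimulus.
#' @param noise_sd observer rating noise (slider units).
#' @param n_factors factor count, `NULL` for Horn's parallel analysis.
#' @param rotation factor rotation flag.
#' @param standardize transfer standardization (`"new"` or `"training"`).
#' @param grid_n,sim_frames,resolution,frame_stride simulator sizes for the
#'   measurement-model comparison (kept modest: the mesh/image measurements
#'   scale linearly in frames and quadratically in grid resolution).
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, repetitions = 4L, noise_sd = 0.05,
                       n_factors = NULL, rotation = "none",
                       standardize = "new", grid_n = 24L, sim_frames = 48L,
                       resolution = c(160L, 120L), frame_stride = 6L,
                       out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), repetitions = repetitions,
              noise_sd = noise_sd, n_factors = n_factors,
              rotation = rotation, standardize = standardize,
              grid_n = grid_n, sim_frames = sim_frames,
              resolution = resolution, frame_stride = frame_stride,
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

## polynomial rolling hash of the deparsed config, stamped into output
## file headers so every artifact is traceable to its configuration
config_hash <- function(config) {
  s <- utf8ToInt(paste(deparse(config[setdiff(names(config), "out_dir")]),
                       collapse = ""))
  h <- 5381
  for (b in s) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_stamped_csv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s", config_hash(config)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

## shared synthetic data for both study directions: Set 1 (pouring, 32
## viscosities x 6 time periods) and Set 2 (7 viscosities x 8 scenes),
## generated from one generative model (same loadings and weights)
generate_study_data <- function(config) {
  d1 <- set1_design()
  d2 <- set2_design()
  truth1 <- make_ground_truth(d1, noise_sd = config$noise_sd,
                              seed = child_seed(config$seed, 1L))
  truth2 <- make_ground_truth(d2, loadings = truth1$loadings,
                              beta = truth1$regression_weights,
                              noise_sd = config$noise_sd,
                              seed = child_seed(config$seed, 2L))
  list(truth1 = truth1, truth2 = truth2,
       feats1 = generate_feature_ratings(truth1, config$repetitions,
                                         seed = child_seed(config$seed, 3L)),
       visc1 = generate_viscosity_ratings(truth1, config$repetitions,
                                          seed = child_seed(config$seed, 4L)),
       feats2 = generate_feature_ratings(truth2, config$repetitions,
                                         seed = child_seed(config$seed, 5L)),
       visc2 = generate_viscosity_ratings(truth2, config$repetitions,
                                          seed = child_seed(config$seed, 6L)))
}

fit_direction <- function(features, viscosity, config) {
  visc_model(features, viscosity, n_factors = config$n_factors,
             rotation = config$rotation, seed = child_seed(config$seed, 7L))
}

#' Run the forward study: train on pouring, transfer to the eight scenes
#'
#' Generates both synthetic stimulus sets, fits the perceptual factor model
#' on Set 1 (192 pouring stimuli), freezes it, transfers it to Set 2 (56
#' stimuli across 8 scenes), and reports training and transfer fits plus a
#' random-predictor bootstrap baseline. With `out_dir` set, rating tables,
#' the model JSON and the fit reports are written (each CSV carries the
#' config hash in a header comment).
#'
#' @param config a [run_config()].
#' @return report bundle: `model`, `train_report`, `transfer`,
#'   `baseline`, `data`.
#' @export
run_forward_study <- function(config = run_config()) {
  dat <- generate_study_data(config)
  model <- fit_direction(dat$feats1, dat$visc1, config)
  transfer <- evaluate_transfer(model, dat$feats2, dat$visc2,
                                standardize = config$standardize)
  y1 <- average_repetitions(dat$visc1)$values[, 1]
  baseline <- bootstrap_random_predictor_baseline(
    y1, n_predictors = c(1L, 4L), n_boot = 200L,
    seed = child_seed(config$seed, 8L))
  out <- list(model = model, train_report = model$report,
              transfer = transfer, baseline = baseline, data = dat,
              config = config)
  if (!is.null(config$out_dir)) write_study_outputs(out, "forward")
  out
}

#' Run the reverse study: train on the eight scenes, transfer to pouring
#'
#' As [run_forward_study()] with the training and transfer roles swapped
#' (the identical synthetic data are used in both directions), plus the
#' representational comparison between the two directions: RDMs of the
#' forward- and reverse-model factor scores on each stimulus set, compared
#' by lower-triangle regression.
#'
#' @param config a [run_config()].
#' @return report bundle: `model` (reverse), `forward_model`,
#'   `train_report`, `transfer`, `rdm_set1`, `rdm_set2`, `data`.
#' @export
run_reverse_study <- function(config = run_config()) {
  dat <- generate_study_data(config)
  fwd <- fit_direction(dat$feats1, dat$visc1, config)
  ## the factor count is a property of the feature set, established once on
  ## the larger training set and shared by both model directions
  rev_config <- config
  rev_config$n_factors <- fwd$n_factors
  rev <- fit_direction(dat$feats2, dat$visc2, rev_config)
  transfer <- evaluate_transfer(rev, dat$feats1, dat$visc1,
                                standardize = config$standardize)
  f1 <- average_repetitions(dat$feats1)
  f2 <- average_repetitions(dat$feats2)
  rdm_cmp <- function(feats) {
    a <- compute_rdm(factor_scores(fwd$factor_model, feats, "new"))
    b <- compute_rdm(factor_scores(rev$factor_model, feats, "new"))
    compare_rdms(a, b)
  }
  out <- list(model = rev, forward_model = fwd, train_report = rev$report,
              transfer = transfer, rdm_set1 = rdm_cmp(f1),
              rdm_set2 = rdm_cmp(f2), data = dat, config = config)
  if (!is.null(config$out_dir)) write_study_outputs(out, "reverse")
  out
}

#' Compare the measurement-based models on the eight-scene set
#'
#' Simulates the 56 Set-2 stimuli as height-field mesh sequences, renders
#' silhouettes, computes the three measurement models — mean optical-flow
#' speed, the 20 silhouette statistics (as the single mean predictor and as
#' a full 20-predictor regression), and the four 3D mesh metrics — and fits
#' each against the simulated viscosity ratings with weights fixed across
#' contexts and free per scene.
#'
#' @param config a [run_config()]; simulator sizes come from it.
#' @return list with `table` (model x mode R-squared data.frame), the per-
#'   model fit objects, and the predictor matrices.
#' @export
run_measurement_model_comparison <- function(config = run_config()) {
  design <- set2_design()
  scenes <- default_scenes(grid_n = config$grid_n)
  truth <- make_ground_truth(design, noise_sd = config$noise_sd,
                             seed = child_seed(config$seed, 2L))
  visc <- average_repetitions(
    generate_viscosity_ratings(truth, config$repetitions,
                               seed = child_seed(config$seed, 6L)))
  y <- visc$values[, 1]

  seqs <- vector("list", nrow(design))
  flow <- numeric(nrow(design))
  stat_rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    sc <- scenes[[design$scene_id[i]]]
    seqs[[i]] <- generate_liquid_sequence(sc, design$viscosity[i],
                                          n_frames = config$sim_frames,
                                          seed = child_seed(config$seed,
                                                            1000L + i))
    keep <- seq(1L, config$sim_frames, by = max(1L, config$frame_stride %/% 2L))
    sub <- seqs[[i]]
    sub$frames <- sub$frames[keep]
    sub$heights <- sub$heights[, , keep, drop = FALSE]
    video <- render_silhouette(sub, resolution = config$resolution)
    flow[i] <- as.numeric(mean_flow_speed(video))
    ## silhouettes of thin films are sparse at low resolution: keep the
    ## pixel threshold proportional to the render area
    min_px <- max(30L, round(300 * prod(config$resolution) / (800 * 600)))
    fr <- filter_frames(video, min_pixels = min_px)
    stat_rows[[i]] <- if (fr$unmeasurable)
      rep(NA_real_, length(silhouette_stat_names))
    else silhouette_statistics(fr$masks)
  }
  stats2d <- do.call(rbind, stat_rows)
  colnames(stats2d) <- silhouette_stat_names
  metrics3d <- extract_metrics(seqs, aggregation = "full_sequence",
                               frame_stride = config$frame_stride)
  m3d <- as.matrix(metrics3d[, c("m1_angular_curvature_z", "m2_flatness_z",
                                 "m3_com_height_z",
                                 "m4_total_abs_curvature_z")])
  mean2d <- stats_mean_predictor(stats2d, train_labels = y)
  norm2d <- apply(stats2d[, apply(stats2d, 2, function(c3)
    all(is.finite(c3)) && stats::sd(c3) > 0), drop = FALSE], 2, minmax_norm)

  fits <- list(
    flow_fixed = fit_measurement_model(flow, y, "fixed_across_contexts"),
    flow_free = fit_measurement_model(flow, y, "free_per_scene",
                                      scene_id = design$scene_id),
    stats2d_mean_fixed = fit_measurement_model(as.numeric(mean2d), y,
                                               "fixed_across_contexts"),
    stats2d_mean_free = fit_measurement_model(as.numeric(mean2d), y,
                                              "free_per_scene",
                                              scene_id = design$scene_id),
    stats2d_full_fixed = fit_measurement_model(norm2d, y,
                                               "fixed_across_contexts"),
    mesh3d_fixed = fit_measurement_model(m3d, y, "fixed_across_contexts"),
    mesh3d_free = fit_measurement_model(m3d, y, "free_per_scene",
                                        scene_id = design$scene_id))
  tab <- data.frame(
    model = c("flow", "flow", "stats2d_mean", "stats2d_mean",
              "stats2d_full", "mesh3d", "mesh3d"),
    mode = c("fixed", "free", "fixed", "free", "fixed", "fixed", "free"),
    r_squared = c(fits$flow_fixed$report$r_squared, fits$flow_free$mean_r2,
                  fits$stats2d_mean_fixed$report$r_squared,
                  fits$stats2d_mean_free$mean_r2,
                  fits$stats2d_full_fixed$report$r_squared,
                  fits$mesh3d_fixed$report$r_squared,
                  fits$mesh3d_free$mean_r2))
  list(table = tab, fits = fits, flow = flow, stats2d = stats2d,
       metrics3d = metrics3d, viscosity_ratings = y, design = design,
       config = config)
}

write_study_outputs <- function(out, label) {
  config <- out$config
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  write_stamped_csv(as.data.frame(out$data$feats1),
                    p(sprintf("%s_features_set1.csv", label)), config)
  write_stamped_csv(as.data.frame(out$data$feats2),
                    p(sprintf("%s_features_set2.csv", label)), config)
  write_stamped_csv(as.data.frame(out$data$visc1),
                    p(sprintf("%s_viscosity_set1.csv", label)), config)
  write_stamped_csv(as.data.frame(out$data$visc2),
                    p(sprintf("%s_viscosity_set2.csv", label)), config)
  write_visc_model(out$model, p(sprintf("%s_model.json", label)))
  reports <- list(config_hash = config_hash(config),
                  train = unclass(out$train_report)[
                    c("r_squared", "f", "df1", "df2", "n", "p_value")],
                  transfer = unclass(out$transfer$report)[
                    c("r_squared", "f", "df1", "df2", "n", "p_value")])
  jsonlite::write_json(reports, p(sprintf("%s_reports.json", label)),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Serialize a fitted viscosity model to JSON
#'
#' Stores loadings, uniquenesses, the training standardization, score
#' weights, regression weights and flags — everything needed to apply the
#' frozen model elsewhere.
#'
#' @param model a [visc_model()].
#' @param path JSON file path.
#' @export
write_visc_model <- function(model, path) {
  fm <- model$factor_model
  obj <- list(loadings = fm$loadings, uniquenesses = fm$uniquenesses,
              score_weights = fm$score_weights,
              standardization = fm$standardization,
              feature_names = fm$feature_names, rotation = fm$rotation,
              n_factors = fm$n_factors, beta = model$beta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_visc_model
#' @export
read_visc_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fm <- structure(list(
    loadings = matrix(unlist(obj$loadings), ncol = obj$n_factors,
                      dimnames = list(obj$feature_names,
                                      paste0("factor_",
                                             seq_len(obj$n_factors)))),
    uniquenesses = stats::setNames(as.numeric(obj$uniquenesses),
                                   obj$feature_names),
    score_weights = matrix(unlist(obj$score_weights),
                           ncol = obj$n_factors,
                           dimnames = list(obj$feature_names,
                                           paste0("factor_",
                                                  seq_len(obj$n_factors)))),
    standardization = list(mean = stats::setNames(
      as.numeric(obj$standardization$mean), obj$feature_names),
      sd = stats::setNames(as.numeric(obj$standardization$sd),
                           obj$feature_names)),
    feature_names = obj$feature_names, n_factors = obj$n_factors,
    rotation = obj$rotation,
    factor_names = paste0("factor_", seq_len(obj$n_factors))),
    class = "factor_model")
  structure(list(factor_model = fm,
                 beta = stats::setNames(as.numeric(obj$beta),
                                        names(obj$beta)),
                 n_factors = obj$n_factors),
            class = "visc_model")
}
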