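#' Pipeline configuration
#'
#' Gathers every stage parameter of the end-to-end synthetic-study
#' pipeline with its default. Unknown keys are rejected.
#'
#' @param n_scenes,target_r,composition,scene_opts study layout, see
#'   [generate_study()].
#' @param sensor_noise apply [add_sensor_noise()] to each scene.
#' @param filter_radius,min_neighbors isolated-point filter parameters.
#' @param height_threshold,exg_threshold,ground_clearance segmentation
#'   parameters, see [select_maize()].
#' @param volume_method `"divergence"` or `"prism"`.
#' @param cda_scheme confusion-matrix scheme, see [cda_confusion()].
#' @param seed master seed; fixes the entire run.
#' @param out_dir optional output directory (CSV tables + JSON report).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_scenes = 10, target_r = 0.85,
                            composition = c(grass = 12, broadleaf = 10,
                                            mixture = 10, none = 8),
                            scene_opts = list(),
                            sensor_noise = TRUE,
                            filter_radius = 0.01, min_neighbors = 1,
                            height_threshold = 0.30, exg_threshold = 20,
                            ground_clearance = 0.02,
                            volume_method = "divergence",
                            cda_scheme = "leave_one_out",
                            seed = 1, out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic-study pipeline
#'
#' Simulate -> sensor noise -> isolated-point filtering -> frame detection
#' -> crop -> quadrat split -> segmentation -> volumetry -> statistics.
#' The report carries the per-quadrat volume table, the six volume
#' relationships, and the weed-class confusion matrices. A fixed seed
#' reproduces the report exactly.
#'
#' @param config a [pipeline_config()].
#' @return List with `volumes`, `truth`, `analysis`, `params`, `seed`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  with_seed(config$seed, run_pipeline_impl(config))
}

run_pipeline_impl <- function(cfg) {
  study <- generate_study(n_scenes = cfg$n_scenes,
                          target_r = cfg$target_r,
                          composition = cfg$composition,
                          scene_opts = cfg$scene_opts, meshes = TRUE,
                          seed = sample.int(.Machine$integer.max, 1))
  scene_cfg <- study$scenes[[1]]$config
  rows <- vector("list", nrow(study$truth))
  ri <- 0L
  for (i in seq_along(study$scenes)) {
    sc <- study$scenes[[i]]
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed for scene %d: %s", what, i,
                     conditionMessage(e)), call. = FALSE))
    }
    m <- sc$mesh
    if (cfg$sensor_noise)
      m <- stage("sensor_noise",
                 add_sensor_noise(m, scene_cfg$depth_noise_sd,
                                  scene_cfg$outlier_fraction,
                                  scene_cfg$dropout_fraction))
    m <- stage("filter", filter_isolated_vertices(m, cfg$filter_radius,
                                                  cfg$min_neighbors))
    fr <- stage("detect_frame", detect_frame(m))
    cropped <- stage("crop", crop_to_frame(m, fr))
    quads <- stage("split", split_quadrats(cropped, fr))
    for (qs in quads) {
      if (n_faces(qs$mesh) == 0) next
      ctr <- colMeans(qs$mesh$vertices)
      tq <- 1L + (ctr[1] >= 0.5) + 2L * (ctr[2] >= 0.5)
      tr <- study$truth[study$truth$scene == i &
                          study$truth$quadrat == tq, ]
      seg <- stage("segment",
                   segment_sample(qs, cfg$height_threshold,
                                  cfg$exg_threshold,
                                  cfg$ground_clearance))
      vr <- stage("volume",
                  quadrat_volume_report(seg, fr$ground_plane,
                                        cfg$volume_method))
      wh <- if (n_vertices(seg$weed_mesh) > 0)
        weed_height_features(seg$weed_mesh, fr$ground_plane)
      else list(max_height = NA_real_, p90_height = NA_real_,
                mean_height = NA_real_)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        sample_id = tr$sample_id, scene = i, quadrat = tq,
        position = tr$position,
        maize_volume_m3 = vr$maize_volume,
        weed_volume_m3 = vr$weed_volume,
        total_volume_m3 = vr$total_volume,
        volume_method = vr$method,
        weed_max_height_m = wh$max_height,
        weed_p90_height_m = wh$p90_height,
        weed_mean_height_m = wh$mean_height,
        stringsAsFactors = FALSE)
    }
  }
  volumes <- do.call(rbind, rows[seq_len(ri)])
  truth_cols <- study$truth[, c("sample_id", "maize_biomass_g",
                                "weed_biomass_g", "weed_density",
                                "weed_class", "maize_count",
                                "true_maize_volume",
                                "true_weed_volume")]
  analysis <- analyze_dataset(volumes, truth_cols)
  report <- list(volumes = volumes, truth = study$truth,
                 analysis = analysis,
                 params = cfg[setdiff(names(cfg), "out_dir")],
                 seed = cfg$seed)
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$volumes, file.path(out_dir, "volumes.csv"),
            row.names = FALSE)
  write.csv(report$truth, file.path(out_dir, "truth.csv"),
            row.names = FALSE)
  json <- list(
    relationships = report$analysis$relationships,
    confusion_loo = as.data.frame.matrix(
      unclass(report$analysis$confusion_loo)),
    confusion_resub = as.data.frame.matrix(
      unclass(report$analysis$confusion_resub)),
    n_samples = report$analysis$n_samples,
    seed = report$seed)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
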