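#' Default end-to-end pipeline configuration
#'
#' Returns the full configuration list driving [run_pipeline()], with every
#' stage's thresholds and hyperparameters. Any subset can be overridden via
#' `...` (or by editing the YAML written with [write_pipeline_config()]).
#' With `simulate = TRUE` the synthetic-scene module generates the inputs;
#' otherwise `scene_paths`, `bathymetry_path` and `habitat_path` name files
#' on disk.
#'
#' @param ... named overrides of the defaults.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    version = "posimap-1",
    out_dir = "posimap_out",
    seed = 1L,
    simulate = TRUE,
    # synthetic scene
    width = 256L, height = 256L, pixel_size = 10, max_depth = 50,
    n_dates = 6L, cover_fraction = 0.35, patch_scale = 24, depth_limit = 40,
    noise_sd = 0.005,
    boat_rate = 0.002, swell_amplitude = 0.01, cloud_fraction = 0.10,
    seasonal_amplitude = 0.01,
    # file inputs (used when simulate = FALSE)
    scene_paths = character(0), bathymetry_path = "", habitat_path = "",
    class_map = list("PO" = 1, "Non-PO" = 0),
    # preprocess
    max_masked_fraction = 0.3, band_anomaly_z = 3.0, min_valid = 3L,
    crop_depth = 40,
    # classifier
    hidden_layers = c(32L, 16L), batch_size = 256L, epochs = 300L,
    learning_rate = 0.05, split_fraction = 0.8,
    # postfilter
    filter_kind = "median", filter_window = 3L, sieve_min_size = 5L,
    bilateral_spatial_sigma = 1.0, bilateral_range_sigma = 0.2,
    pca_components = 2L,
    # assessment
    depth_bins = list(c(0, 25), c(25, 40)),
    assess_on = "validation")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return a `pipeline_config` / `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$depth_bins <- lapply(raw$depth_bins, function(b) as.numeric(unlist(b)))
  if (!is.null(raw$hidden_layers)) raw$hidden_layers <- unlist(raw$hidden_layers)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(cfg) {
  if (!isTRUE(cfg$simulate)) {
    if (!length(cfg$scene_paths)) stop("config error: scene_paths is empty")
    if (!nzchar(cfg$bathymetry_path))
      stop("config error: bathymetry_path is missing")
    if (!nzchar(cfg$habitat_path)) stop("config error: habitat_path is missing")
  }
  stopifnot(cfg$split_fraction > 0, cfg$split_fraction < 1,
            cfg$crop_depth > 0, cfg$min_valid >= 1)
  invisible(cfg)
}

#' Run the full mapping pipeline
#'
#' Executes screen, median stack, bathymetry resampling, depth crop, label
#' rasterization, feature extraction, train/validation split, classifier
#' training, map prediction, post-filtering and accuracy assessment, writing
#' every intermediate product under `config$out_dir` with an MD5 checksum in
#' the returned manifest. Reruns with an identical configuration are
#' bit-reproducible. No stage mutates its inputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage log lines.
#' @return list with `manifest` (data.frame of stage, path, md5), `report`
#'   (the `accuracy_report`), `model`, and the key rasters.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(stage = character(0), path = character(0),
                         md5 = character(0))
  log_stage <- function(stage, msg) {
    if (!quiet) message(sprintf("[%s] %s", stage, msg))
  }
  emit <- function(stage, obj, file) {
    path <- file.path(cfg$out_dir, file)
    write_raster(obj, path)
    files <- path
    if (grepl("\\.json$", path))  # manifest + its band files
      files <- c(path, file.path(cfg$out_dir, sprintf(
        "%s_b%d.asc", sub("\\.json$", "", basename(path)), seq_len(n_bands(obj)))))
    for (f in files) {
      manifest[nrow(manifest) + 1L, ] <<-
        list(stage, f, unname(tools::md5sum(f)))
    }
    log_stage(stage, paste("wrote", basename(path)))
  }

  if (isTRUE(cfg$simulate)) {
    bathy_fine <- generate_bathymetry(cfg$width, cfg$height, cfg$max_depth,
                                      cfg$pixel_size, seed = cfg$seed)
    habitat <- generate_habitat_map(bathy_fine, cfg$cover_fraction,
                                    cfg$patch_scale, cfg$depth_limit,
                                    seed = cfg$seed + 1L)
    optics <- optics_params(noise_sd = rep(cfg$noise_sd, 3L))
    arts <- artifact_spec(cfg$boat_rate, cfg$swell_amplitude,
                          cfg$cloud_fraction, cfg$seasonal_amplitude,
                          seed = cfg$seed + 2L)
    stack <- simulate_time_series(habitat, bathy_fine, optics, arts,
                                  cfg$n_dates)
    # emulate the coarse external bathymetry product: the fine grid is the
    # truth, the pipeline only ever sees a resampled version of it
    bathy_in <- bathy_fine
    labels_in <- habitat
    log_stage("simulate", sprintf("%dx%d px, %d dates", cfg$height, cfg$width,
                                  cfg$n_dates))
  } else {
    stack <- scene_stack(lapply(cfg$scene_paths, read_raster))
    bathy_in <- read_raster(cfg$bathymetry_path)
    labels_in <- NULL
    log_stage("load", sprintf("%d scenes", length(stack$scenes)))
  }

  stack <- screen_images(stack, cfg$max_masked_fraction, cfg$band_anomaly_z)
  log_stage("screen", sprintf("%d dates retained", length(stack$scenes)))
  composite <- median_stack(stack, cfg$min_valid)
  emit("stack", composite, "composite.json")

  target <- stack$scenes[[1L]]
  bathy <- if (identical(grid_dim(bathy_in), grid_dim(target)))
    bathy_in else resample_bathymetry(bathy_in, target)
  emit("resample", bathy, "bathymetry.asc")

  composite <- apply_depth_mask(composite, bathy, cfg$crop_depth)
  emit("mask", composite, "composite_cropped.json")

  labels <- if (is.null(labels_in)) {
    rasterize_habitat(read_habitat_geojson(cfg$habitat_path), target,
                      unlist(cfg$class_map))
  } else labels_in
  labels <- apply_depth_mask(labels, bathy, cfg$crop_depth)
  emit("rasterize", labels, "labels.asc")

  table_lab <- build_feature_table(composite, bathy, labels)
  table_all <- build_feature_table(composite, bathy)
  log_stage("features", sprintf("%d labelled / %d total pixels",
                                nrow(table_lab), nrow(table_all)))

  tc <- training_config(cfg$batch_size, cfg$epochs, cfg$learning_rate,
                        cfg$split_fraction, cfg$seed + 3L)
  fit <- train_classifier(table_lab, cfg$hidden_layers, tc)
  model_path <- file.path(cfg$out_dir, "model.json")
  save_model(fit$model, model_path)
  manifest[nrow(manifest) + 1L, ] <-
    list("train", model_path, unname(tools::md5sum(model_path)))
  log_stage("train", sprintf("best validation loss %.4f",
                             min(fit$history$val_loss)))

  pred <- predict_map(fit$model, table_all, target)
  emit("predict", pred, "prediction_raw.asc")

  filtered <- switch(cfg$filter_kind,
                     median = median_filter(pred, cfg$filter_window),
                     sieve = sieve_filter(pred, cfg$sieve_min_size),
                     bilateral = bilateral_filter(pred,
                                                  cfg$bilateral_spatial_sigma,
                                                  cfg$bilateral_range_sigma,
                                                  cfg$filter_window),
                     none = pred,
                     stop("config error: unknown filter_kind ",
                          cfg$filter_kind))
  emit("filter", filtered, "prediction.asc")

  assess_pred <- filtered
  assess_truth <- labels
  if (identical(cfg$assess_on, "validation")) {
    # restrict truth to the 20% validation pixels
    d <- grid_dim(labels)
    keep <- matrix(FALSE, d[1L], d[2L])
    keep[cbind(fit$validation$row, fit$validation$col)] <- TRUE
    assess_truth$mask <- labels$mask & keep
  }
  report <- stratified_accuracy(assess_pred, assess_truth, bathy,
                                cfg$depth_bins)
  report_path <- file.path(cfg$out_dir, "accuracy.json")
  jsonlite::write_json(report_to_list(report, cfg$assess_on), report_path,
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  manifest[nrow(manifest) + 1L, ] <-
    list("assess", report_path, unname(tools::md5sum(report_path)))
  emit("assess", performance_map(assess_pred, assess_truth),
       "performance.asc")
  log_stage("assess", sprintf("overall accuracy %.3f on %s pixels",
                              report$overall, cfg$assess_on))

  list(manifest = manifest, report = report, model = fit$model,
       history = fit$history, composite = composite, bathymetry = bathy,
       labels = labels, prediction = filtered)
}

report_to_list <- function(report, assessed_on) {
  strip <- function(x) x[intersect(c("depth_low", "depth_high", "tp", "tn",
                                     "fp", "fn", "n", "overall", "producers",
                                     "users"), names(x))]
  c(list(assessed_on = assessed_on), strip(unclass(report)),
    list(strata = lapply(report$strata, strip)))
}
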