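#' Load and validate a run configuration
#'
#' Configurations are JSON with stage-parameter blocks; every numeric
#' parameter is validated against its stage's preconditions at load time,
#' and the full parameter set is echoed into the run log.
#'
#' @param config path to a JSON file or an already-parsed list.
#' @return Validated config list with class `run_config`.
#' @export
load_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a file path or a list")
  defaults <- list(pixel_size = 1, frame_interval = 10, seed = 1,
                   stages = "measure", min_area = 0,
                   rolling_ball_radius = 50, threshold = "otsu",
                   gate = 20, smooth_sigma = 1,
                   min_filopodium_length = 0.5, min_tip_curvature = 2)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (config$pixel_size <= 0) stop("config error: pixel_size must be > 0")
  if (config$frame_interval <= 0)
    stop("config error: frame_interval must be > 0")
  if (config$rolling_ball_radius < 1)
    stop("config error: rolling_ball_radius must be >= 1")
  if (config$gate <= 0) stop("config error: gate must be > 0")
  if ("migrate" %in% config$stages && is.null(config$frame_interval_migration))
    stop("config error: migration run needs `frame_interval_migration`")
  class(config) <- c("run_config", class(config))
  config
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in order `segment -> measure ->
#' (spreading | migrate) -> validate` on a TIFF input, writing masks, shape
#' CSVs, metric CSVs, a validation JSON and a log that echoes the full
#' configuration, its hash, the seed and per-stage platelet counts. Rerun
#' with an identical configuration reproduces all deterministic outputs.
#'
#' @param config a [load_config()] result, list, or JSON path. Recognised
#'   fields include `input` (TIFF path), `model` (RDS path of a trained
#'   `platelet_unet`, required for the segment stage), `output_dir`,
#'   `stages`, `pixel_size`, `frame_interval`, `seed` and stage parameters.
#' @return Invisible list of produced file paths and tables.
#' @export
run_pipeline <- function(config) {
  config <- load_config(config)
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("platemorph run | config hash %s | seed %d", config_hash(config),
       as.integer(config$seed))
  logf("config: %s", jsonlite::toJSON(unclass(config), auto_unbox = TRUE))
  results <- list(log = log_path)
  masks <- NULL
  if ("segment" %in% config$stages) {
    if (is.null(config$model))
      stop("stage `segment` failed: config needs a `model` checkpoint path")
    model <- readRDS(config$model)
    imgs <- read_image_stack(config$input, config$pixel_size)
    masks <- lapply(imgs, function(im) predict(model, im))
    mask_path <- file.path(out_dir, "masks.tif")
    write_image_stack(masks, mask_path)
    logf("segment: %d frame(s) -> %s", length(masks), mask_path)
    results$masks <- mask_path
  } else if (!is.null(config$input)) {
    masks <- read_mask_stack(config$input, config$pixel_size)
  }
  records <- NULL
  if ("measure" %in% config$stages) {
    if (is.null(masks)) stop("stage `measure` failed: no masks available")
    records <- measure_masks(masks, min_area = config$min_area,
                             smooth_sigma = config$smooth_sigma,
                             min_filopodium_length = config$min_filopodium_length,
                             min_tip_curvature = config$min_tip_curvature)
    shape_path <- file.path(out_dir, "shapes.csv")
    write.csv(records, shape_path, row.names = FALSE)
    logf("measure: %d record(s), %d platelet id(s) -> %s", nrow(records),
         length(unique(records$platelet_id)), shape_path)
    results$shapes <- shape_path
  }
  if ("spreading" %in% config$stages) {
    if (is.null(records)) stop("stage `spreading` failed: no shape records")
    met <- spreading_metrics(records, config$frame_interval)
    p <- file.path(out_dir, "spreading_metrics.csv")
    write.csv(met, p, row.names = FALSE)
    logf("spreading: %d platelet(s), %d censored -> %s", nrow(met),
         sum(met$status == "censored"), p)
    results$spreading <- p
  }
  if ("migrate" %in% config$stages) {
    if (is.null(masks)) stop("stage `migrate` failed: no masks available")
    tracks <- link_tracks(masks, gate = config$gate,
                          min_area = config$min_area)
    fi <- config$frame_interval_migration %||% 30
    met <- migration_metrics(tracks, fi)
    tr_rows <- do.call(rbind, lapply(tracks, function(tr)
      data.frame(platelet_id = tr$platelet_id, frame = tr$frames,
                 x_um = tr$positions[, 1], y_um = tr$positions[, 2],
                 complete = tr$complete)))
    tp <- file.path(out_dir, "tracks.csv")
    mp <- file.path(out_dir, "migration_metrics.csv")
    write.csv(tr_rows, tp, row.names = FALSE)
    write.csv(met, mp, row.names = FALSE)
    logf("migrate: %d track(s), %d complete -> %s", length(tracks),
         sum(vapply(tracks, `[[`, logical(1), "complete")), mp)
    results$tracks <- tp
    results$migration <- mp
  }
  if ("validate" %in% config$stages) {
    if (is.null(config$truth))
      stop("stage `validate` failed: config needs `truth` mask path")
    truth <- read_mask_stack(config$truth, config$pixel_size)
    if (is.null(masks)) stop("stage `validate` failed: no masks available")
    conf <- Map(pixel_confusion, masks, truth)
    pooled <- list(tp = sum(vapply(conf, `[[`, numeric(1), "tp")),
                   fp = sum(vapply(conf, `[[`, numeric(1), "fp")),
                   fn = sum(vapply(conf, `[[`, numeric(1), "fn")))
    pooled$iou <- pooled$tp / (pooled$tp + pooled$fp + pooled$fn)
    vp <- file.path(out_dir, "validation.json")
    jsonlite::write_json(list(config_hash = config_hash(config),
                              pixel_confusion = pooled),
                         vp, auto_unbox = TRUE, digits = NA)
    logf("validate: pooled IoU %.4f -> %s", pooled$iou, vp)
    results$validation <- vp
  }
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
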