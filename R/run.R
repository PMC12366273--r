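#' Read a run configuration file
#'
#' Run configurations are YAML with two optional top-level sections,
#' `simulate` and `morphometry`, mirroring the arguments of
#' [run_simulate()] and [run_morphometry()]. Relative paths are resolved
#' against the config file's directory.
#'
#' @param path YAML file path.
#' @return Named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  cfg$`_dir` <- dirname(normalizePath(path))
  class(cfg) <- "run_config"
  cfg
}

# md5 of the canonical YAML serialisation of a config list
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  cfg <- config[setdiff(names(config), "_dir")]
  yaml::write_yaml(cfg[order(names(cfg))], tmp, precision = 15L)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(out_dir, config, seed, outputs) {
  manifest <- list(
    config_hash = config_hash(config),
    package = "gradientchip",
    version = as.character(utils::packageVersion("gradientchip")),
    seed = seed,
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

resolve_media <- function(name_or_map, media_set, factor_set) {
  if (is.character(name_or_map)) {
    m <- media_set[[name_or_map]]
    if (is.null(m)) stop("unknown media name: ", name_or_map, call. = FALSE)
    m
  } else {
    media_composition("custom", unlist(name_or_map), factor_set)
  }
}

#' Run a gradient simulation and write its design report
#'
#' Drives the full design pipeline from a configuration list: simulate all
#' factors of a counter-current media pair over the chip, derive per-factor
#' distribution reports and limiting factors per side, and write field
#' CSVs, heatmap PNGs, a JSON design report and a run manifest. Outputs are
#' deterministic: rerunning the same configuration reproduces them
#' byte-for-byte.
#'
#' @param config A list (or `run_config` from [read_run_config()], using
#'   its `simulate` section) with elements: `media` (list with `left` and
#'   `right`, each a media name from [default_media()] or a factor->ng/mL
#'   map), `duration_days` (default 2), `snapshot_interval_h` (default 0.5),
#'   `grid_spacing_mm` (default 0.05), optional `geometry`
#'   (`length_mm`, `width_mm`, `channel_segment_length_mm`), optional
#'   `factors_csv` (alternative parameter table), `schedule`
#'   (`"single_loading"`, default, or `"gradient"` for the 31-day protocol)
#'   and `heatmap_times_h` (default none).
#' @param out_dir Output directory.
#' @param seed Recorded in the manifest (the simulation itself is
#'   deterministic).
#' @return Invisible list with `result` (a `simulation_result`), `reports`
#'   (per-factor `distribution_report`s) and `limiting` (per side).
#' @export
run_simulate <- function(config, out_dir, seed = 1) {
  if (inherits(config, "run_config")) config <- config$simulate
  if (is.null(config$media) || is.null(config$media$left) ||
      is.null(config$media$right))
    stop("config must name media for both the left and right reservoir",
         call. = FALSE)
  factor_set <- if (!is.null(config$factors_csv))
    default_growth_factors(config$factors_csv) else default_growth_factors()
  media_set <- default_media(factor_set)
  geom_cfg <- config$geometry
  geometry <- chip_geometry(
    length = geom_cfg$length_mm %||% 7.9,
    width = geom_cfg$width_mm %||% 1.3,
    channel_segment_length = geom_cfg$channel_segment_length_mm %||% 2.6)
  grid <- sim_grid(geometry, config$grid_spacing_mm %||% 0.05)
  duration <- (config$duration_days %||% 2) * 86400
  snap <- (config$snapshot_interval_h %||% 0.5) * 3600
  pair <- list(left = resolve_media(config$media$left, media_set, factor_set),
               right = resolve_media(config$media$right, media_set, factor_set))
  schedule <- if (identical(config$schedule, "gradient"))
    build_gradient_schedule(media_set,
                            duration_days = duration / 86400) else NULL

  result <- simulate_media(pair, geometry, schedule, grid, duration, snap,
                           factor_set)
  side_of <- function(f)
    if (f %in% names(pair$left$factors)) "left" else "right"
  reports <- lapply(names(result$fields), function(f)
    distribution_report(result$fields[[f]], side_of(f),
                        factor_set = factor_set))
  names(reports) <- names(result$fields)
  limiting <- lapply(stats::setNames(c("left", "right"), c("left", "right")),
                     function(s)
    tryCatch(limiting_factor(result, s, factor_set),
             error = function(e) NULL))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  for (f in names(result$fields)) {
    p <- file.path(out_dir, paste0("field_", gsub("[^A-Za-z0-9-]", "_", f), ".csv"))
    write_field_csv(result$fields[[f]], p)
    outputs <- c(outputs, basename(p))
    for (th in config$heatmap_times_h %||% numeric(0)) {
      hp <- file.path(out_dir, sprintf("heatmap_%s_%gh.png",
                                       gsub("[^A-Za-z0-9-]", "_", f), th))
      plot_field_heatmap(result$fields[[f]], th, hp,
                         ec50 = factor_set[[f]]$ec50)
      outputs <- c(outputs, basename(hp))
    }
  }
  write_distribution_reports(reports,
                             json_path = file.path(out_dir, "design_report.json"),
                             csv_path = file.path(out_dir, "distribution_timeseries.csv"))
  lim <- lapply(limiting, function(l)
    if (is.null(l)) NULL else list(factor = l$factor,
                                   max_distances_mm = as.list(l$max_distances)))
  jsonlite::write_json(lim, file.path(out_dir, "limiting_factors.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  outputs <- c(outputs, "design_report.json", "distribution_timeseries.csv",
               "limiting_factors.json")
  write_manifest(out_dir, config, seed, sort(outputs))
  invisible(list(result = result, reports = reports, limiting = limiting))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run morphometry over a directory or list of images
#'
#' Applies vessel morphometry and/or lipid-coverage quantification to each
#' image and writes per-image CSVs. Unreadable or failing images are
#' skipped with a recorded error; the run continues and the error count is
#' reported.
#'
#' @param config List with elements: `images` (character vector of paths,
#'   or a directory to scan for `.tif`/`.tiff`/`.png`), `pixel_size_um`
#'   (required), `analysis` (`"vessels"`, `"lipid"` or both; default
#'   `"vessels"`), optional `subsample` and `endpoint_mode` (frames are
#'   ordered by filename and treated as a time-lapse when `subsample` > 1),
#'   plus optional `intensity_threshold`, `min_particle_area_um2`,
#'   `max_hole_area_um2`, `lipid_threshold_band`, `bin_width_um`.
#' @param out_dir Output directory.
#' @param seed Recorded in the manifest.
#' @return Invisible list with `vessels` and `lipid` data frames (or
#'   `NULL`), and `errors` (named character vector per failed file).
#' @export
run_morphometry <- function(config, out_dir, seed = 1) {
  if (inherits(config, "run_config")) config <- config$morphometry
  px_size <- config$pixel_size_um
  if (is.null(px_size)) stop("config must give pixel_size_um", call. = FALSE)
  imgs <- config$images
  if (length(imgs) == 1L && dir.exists(imgs))
    imgs <- sort(list.files(imgs, pattern = "\\.(tif|tiff|png)$",
                            ignore.case = TRUE, full.names = TRUE))
  analysis <- config$analysis %||% "vessels"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  errors <- character(0)
  frames <- list()
  for (p in imgs) {
    fr <- tryCatch(read_image_frame(p, px_size), error = function(e) e)
    if (inherits(fr, "error")) {
      errors[p] <- conditionMessage(fr)
      warning("skipping unreadable image: ", p, call. = FALSE)
    } else frames[[p]] <- fr
  }

  vessels <- lipid <- NULL
  if ("vessels" %in% analysis) {
    if (length(frames)) {
      vessels <- timeseries_metrics(
        unname(frames), subsample = config$subsample %||% 1,
        endpoint_mode = config$endpoint_mode %||% "complete",
        intensity_threshold = config$intensity_threshold,
        min_particle_area = config$min_particle_area_um2 %||% 500,
        max_hole_area = config$max_hole_area_um2 %||% 100)
      vessels$file <- basename(names(frames))[vessels$frame]
    } else {
      vessels <- data.frame(frame = integer(0), timestamp = numeric(0),
                            n_junctions = integer(0), n_endpoints = integer(0),
                            total_length = numeric(0), total_area = numeric(0),
                            file = character(0))
      warning("no readable images: writing empty vessel metrics",
              call. = FALSE)
    }
    utils::write.csv(vessels, file.path(out_dir, "vessel_metrics.csv"),
                     row.names = FALSE)
  }
  if ("lipid" %in% analysis) {
    rows <- lapply(names(frames), function(p) {
      prof <- tryCatch(
        lipid_coverage(frames[[p]],
                       threshold_band = config$lipid_threshold_band,
                       bin_width = config$bin_width_um %||% 370),
        error = function(e) e)
      if (inherits(prof, "error")) {
        errors[p] <<- conditionMessage(prof)
        return(NULL)
      }
      data.frame(file = basename(p), whole_pct = prof$whole,
                 vasculogenesis_pct = prof$thirds[["vasculogenesis"]],
                 middle_pct = prof$thirds[["middle"]],
                 adipogenesis_pct = prof$thirds[["adipogenesis"]])
    })
    lipid <- do.call(rbind, rows)
    if (is.null(lipid))
      lipid <- data.frame(file = character(0), whole_pct = numeric(0),
                          vasculogenesis_pct = numeric(0),
                          middle_pct = numeric(0),
                          adipogenesis_pct = numeric(0))
    utils::write.csv(lipid, file.path(out_dir, "lipid_coverage.csv"),
                     row.names = FALSE)
  }
  write_manifest(out_dir, config, seed,
                 sort(list.files(out_dir, pattern = "\\.csv$")))
  invisible(list(vessels = vessels, lipid = lipid, errors = errors))
}
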