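#' Write / read a thermal stack
#'
#' `write_stack` stores the frames as a multi-page 32-bit TIFF (values
#' linearly scaled to \[0, 1\]; scale recorded in the sidecar) plus a
#' JSON sidecar `<path>.json` with frame rate, pixel size, origin and
#' baseline temperature. `read_stack` reads that format back
#' (`dialect = "tiff"`), or ingests vendor-style per-frame CSV exports
#' (`dialect = "csv_frames"`): one frame per file, comma-separated
#' temperatures in degC, files taken in lexicographic order, with
#' `skip` header lines ignored in each file; metadata then comes from
#' `meta` (or a `<dir>/meta.json` file), which must name `f_rate` and
#' `pixel_size`.
#'
#' @param stack a [thermal_stack()].
#' @param path TIFF file path (for `write_stack` / `dialect = "tiff"`)
#'   or a directory of per-frame CSV files.
#' @param dialect `"tiff"` or `"csv_frames"`.
#' @param meta named list of metadata for the CSV dialect (`f_rate`,
#'   `pixel_size`, optional `origin`, `T0`).
#' @param skip header lines to skip in each CSV file.
#' @return `write_stack` returns `path` invisibly; `read_stack` a
#'   [thermal_stack()].
#' @export
write_stack <- function(stack, path) {
  .assert(inherits(stack, "thermal_stack"), "`stack` must be a thermal_stack")
  lo <- min(stack$frames); hi <- max(stack$frames)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(stack$frames)[3]), function(k) {
    (stack$frames[, , k] - lo) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(list(f_rate = stack$f_rate, pixel_size = stack$pixel_size,
                            origin = stack$origin, T0 = stack$T0,
                            value_min = lo, value_scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, dialect = c("tiff", "csv_frames"), meta = NULL,
                       skip = 0) {
  dialect <- match.arg(dialect)
  if (dialect == "tiff") {
    side_path <- paste0(path, ".json")
    .assert(file.exists(side_path), sprintf("missing sidecar '%s'", side_path))
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) {
      frames[, , k] <- pages[[k]] * side$value_scale + side$value_min
    }
    meta <- side
  } else {
    files <- if (dir.exists(path)) {
      sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    } else {
      sort(path)
    }
    .assert(length(files) > 0, "no CSV frame files found")
    if (is.null(meta)) {
      mj <- file.path(if (dir.exists(path)) path else dirname(files[1]), "meta.json")
      .assert(file.exists(mj),
              "CSV stacks need `meta` (or a meta.json next to the frames)")
      meta <- jsonlite::read_json(mj, simplifyVector = TRUE)
    }
    mats <- lapply(files, function(f) {
      as.matrix(read.csv(f, header = FALSE, skip = skip))
    })
    d1 <- dim(mats[[1]])
    same <- vapply(mats, function(m) identical(dim(m), d1), logical(1))
    if (!all(same)) {
      stop(sprintf("frame shape mismatch: '%s' differs from '%s'",
                   basename(files[which(!same)[1]]), basename(files[1])),
           call. = FALSE)
    }
    frames <- array(unlist(mats), dim = c(d1, length(mats)))
  }
  for (key in c("f_rate", "pixel_size")) {
    if (is.null(meta[[key]])) {
      stop(sprintf("missing required metadata key '%s'", key), call. = FALSE)
    }
  }
  thermal_stack(frames, f_rate = meta$f_rate, pixel_size = meta$pixel_size,
                origin = unlist(meta$origin %||% c(0, 0)),
                T0 = meta$T0 %||% NA_real_)
}

# --- run configuration -------------------------------------------------------

config_schema <- list(
  scene = c("type", "stripe_width", "gap", "n_stripes", "pitch", "margin",
            "height", "n_clusters", "cluster_radius", "field", "side", "path"),
  sample = c("preset", "emissivity", "diffusivity", "T0", "A", "tau_d"),
  beam = c("wavelength", "power", "diameter_1e2"),
  protocol = c("n_x", "n_y", "pixel_size", "lattice", "tau_on", "tau_off",
               "origin"),
  camera = c("pixel_size", "format", "f_rate", "netd", "psf_fwhm",
             "photon_gain", "background", "distance", "fov"),
  detection = c("window", "amp_threshold"),
  localization = c("model", "fit_roi", "zeta0_sq"),
  rendering = c("dT_min"),
  noise = NULL, seed = NULL, target_dT = NULL
)

#' Read and validate a pipeline configuration
#'
#' Configurations are YAML with nested sections (`scene`, `sample`,
#' `beam`, `protocol`, `camera`, `detection`, `localization`,
#' `rendering`) plus top-level `noise`, `seed` and optional `target_dT`.
#' Unknown keys are rejected so that typos do not silently fall back to
#' defaults.
#'
#' @param path YAML file path.
#' @param config a configuration list (as from `read_run_config`).
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  .assert(is.list(config), "config must be a list")
  unknown <- setdiff(names(config), names(config_schema))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (sec in names(config)) {
    allowed <- config_schema[[sec]]
    if (is.null(allowed)) next
    .assert(is.list(config[[sec]]), sprintf("config section '%s' must be a mapping", sec))
    bad <- setdiff(names(config[[sec]]), allowed)
    if (length(bad)) {
      stop(sprintf("unknown keys in config section '%s': %s",
                   sec, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  .assert(!is.null(config$protocol), "config must contain a `protocol` section")
  .assert(!is.null(config$scene), "config must contain a `scene` section")
  config
}

build_scene <- function(sc) {
  switch(sc$type,
    stripes = make_stripe_grid(sc$stripe_width, sc$gap, sc$n_stripes, sc$pitch,
                               margin = sc$margin %||% ((sc$stripe_width + sc$gap) / 2),
                               height = sc$height),
    clusters = make_sparse_clusters(sc$n_clusters, sc$cluster_radius,
                                    unlist(sc$field), sc$seed %||% 1, sc$pitch),
    square = make_uniform_square(sc$side, sc$pitch,
                                 field = sc$field %||% (2 * sc$side)),
    tiff = read_absorber_map(sc$path),
    stop(sprintf("unknown scene type '%s'", sc$type), call. = FALSE))
}

build_sample <- function(sm) {
  sm <- sm %||% list()
  preset <- sm$preset %||% "ink"
  sm$preset <- NULL
  do.call(if (preset == "biopsy") sample_biopsy else sample_ink, sm)
}

#' Run the full imaging pipeline
#'
#' Simulate, detect, localize, render and assess in one call: builds the
#' scene and schedule from the configuration, renders the noisy camera
#' stack, detects temperature peaks in the per-pixel traces, localizes
#' them with the configured fit, bins the localizations into the
#' super-resolution image, and writes every artifact (stack, schedule,
#' events, localizations, super-resolution and max-projection images, a
#' JSON report with stage counters, and a text log) into `out_dir`.
#' The run is deterministic given the seed.
#'
#' @param config configuration list (see [read_run_config()]).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed; overrides `config$seed`.
#' @return Invisibly, a list with the in-memory artifacts (`stack`,
#'   `schedule`, `events`, `locs`, `sr`, `lowres`, `report`).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  config <- validate_run_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%OS1"), sprintf(...)),
        file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_line("stage %s FAILED: %s", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  log_line("run start, seed %d, config md5 %s", seed, cfg_hash)

  map <- stage("scene", build_scene(config$scene))
  sample <- stage("sample", build_sample(config$sample))
  beam <- stage("beam", do.call(beam_model, config$beam %||% list()))
  camera <- stage("camera", do.call(camera_model, config$camera %||% list()))
  proto <- stage("protocol", do.call(scan_protocol, config$protocol))
  schedule <- stage("schedule", build_schedule(proto))
  log_line("schedule: %d events over %.1f s", nrow(schedule), total_time(proto))

  tau_on <- proto$tau_on
  if (!is.null(config$target_dT)) {
    # calibrate on a known absorbing spot: the first ground-truth feature
    # if the scene records one, otherwise the field center
    cal_loc <- if (!is.null(map$centers) && nrow(map$centers) > 0) {
      unlist(map$centers[1, c("x", "y")])
    } else {
      map$origin + c(ncol(map$values), nrow(map$values)) * map$pitch / 2
    }
    sample <- stage("amplitude calibration",
                    calibrate_amplitude(map, sample, beam, camera,
                                        location = cal_loc,
                                        tau_on, config$target_dT))
    log_line("amplitude calibrated: A = %.4g degC/s", sample$A)
  }
  noise <- config$noise %||% "photon"
  stack <- stage("render", render_stack(map, sample, beam, schedule, camera,
                                        noise = noise, seed = seed))
  log_line("stack: %d frames of %d x %d px", dim(stack)[3], dim(stack)[1], dim(stack)[2])

  det_cfg <- config$detection %||% list()
  window <- det_cfg$window %||% default_window(tau_on, camera$f_rate)
  amp_threshold <- det_cfg$amp_threshold %||% (3 * camera$netd)
  events <- stage("detect", detect_stack_events(stack, window = window,
                                                amp_threshold = amp_threshold))
  log_line("detected %d events (window %d, threshold %.2f degC)",
           nrow(events), window, amp_threshold)

  loc_cfg <- config$localization %||% list()
  zeta0_sq <- loc_cfg$zeta0_sq %||% default_zeta0_sq(sample, beam, camera, tau_on)
  locs <- stage("localize",
                localize_events(stack, events, zeta0_sq,
                                model = loc_cfg$model %||% "two_step",
                                fit_roi = loc_cfg$fit_roi %||% 11,
                                sample = sample))
  log_line("localized %d events (%d dropped)", nrow(locs), attr(locs, "n_dropped"))

  dT_min <- (config$rendering %||% list())$dT_min %||% 0.3
  sr <- stage("render image", bin_localizations(locs, proto, dT_min = dT_min))
  lowres <- stage("max projection", max_projection(stack))

  report <- list(
    seed = seed, config_md5 = cfg_hash,
    n_events_scheduled = nrow(schedule), n_events_detected = nrow(events),
    n_localized = nrow(locs), n_fit_dropped = attr(locs, "n_dropped"),
    n_outside_grid = sr$n_outside, n_rendered_pixels = sum(sr$values > 0),
    dT_min = dT_min, total_time_s = total_time(proto))

  write_stack(stack, file.path(out_dir, "stack.tif"))
  write_schedule(schedule, file.path(out_dir, "schedule.csv"))
  write_events(events, file.path(out_dir, "events.csv"))
  write_localizations(locs, file.path(out_dir, "localizations.csv"))
  write_superres(sr, file.path(out_dir, "superres.tif"))
  tiff::writeTIFF((unclass(lowres) - min(lowres)) / max(1e-12, diff(range(lowres))),
                  file.path(out_dir, "lowres_maxproj.tif"), bits.per.sample = 32L)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line("run complete: %d rendered pixels", report$n_rendered_pixels)
  invisible(list(stack = stack, schedule = schedule, events = events,
                 locs = locs, sr = sr, lowres = lowres, report = report))
}
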