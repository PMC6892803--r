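#!/usr/bin/env Rscript
# Thin command-line driver for the thermoloc pipeline.
#
#   Rscript scripts/thermoloc.R pipeline --config run.yaml --out out/ [--seed 1]
#   Rscript scripts/thermoloc.R simulate --config run.yaml --out out/ [--seed 1]
#
# `pipeline` runs simulate -> detect -> localize -> render -> report;
# `simulate` stops after writing the synthetic camera stack.

suppressPackageStartupMessages({
  library(optparse)
  library(thermoloc)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !args[1] %in% c("pipeline", "simulate")) {
  stop("usage: thermoloc.R <pipeline|simulate> --config <yaml> --out <dir> [--seed <int>]")
}
cmd <- args[1]

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character"),
  make_option("--out", type = "character", default = "thermoloc_out"),
  make_option("--seed", type = "integer", default = NULL)
)), args = args[-1])

if (is.null(opts$config)) stop("--config is required")
config <- read_run_config(opts$config)

if (cmd == "simulate") {
  # run the forward model only: build the scene and schedule, render the
  # stack, write it with its schedule
  seed <- as.integer(opts$seed %||% config$seed %||% 1)
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  map <- thermoloc:::build_scene(config$scene)
  sample <- thermoloc:::build_sample(config$sample)
  beam <- do.call(beam_model, config$beam %||% list())
  camera <- do.call(camera_model, config$camera %||% list())
  proto <- do.call(scan_protocol, config$protocol)
  schedule <- build_schedule(proto)
  if (!is.null(config$target_dT) && !is.null(map$centers) && nrow(map$centers)) {
    sample <- calibrate_amplitude(map, sample, beam, camera,
                                  unlist(map$centers[1, c("x", "y")]),
                                  proto$tau_on, config$target_dT)
  }
  stack <- render_stack(map, sample, beam, schedule, camera,
                        noise = config$noise %||% "photon", seed = seed)
  write_stack(stack, file.path(opts$out, "stack.tif"))
  write_schedule(schedule, file.path(opts$out, "schedule.csv"))
  write_absorber_map(map, file.path(opts$out, "scene.tif"))
  cat(sprintf("simulated %d frames -> %s\n", dim(stack)[3], opts$out))
} else {
  out <- run_pipeline(config, opts$out, seed = opts$seed)
  cat(sprintf("pipeline complete: %d events, %d localized, %d rendered px -> %s\n",
              out$report$n_events_detected, out$report$n_localized,
              out$report$n_rendered_pixels, opts$out))
}
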