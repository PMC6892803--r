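# Shared fixtures: all built in code at test time.

# Default 22 um beam and a small camera cut-out of the standard geometry.
test_beam <- function() beam_model(diameter_1e2 = 22)
test_camera <- function(format = c(13, 13)) camera_model(format = format)

# Uniform-absorber setup for repeatability runs: 800 um ink square,
# beam parked at its center, amplitude calibrated to `target_dT`.
square_setup <- function(target_dT = 2, tau_on = 0.3) {
  map <- make_uniform_square(800, 5)
  beam <- test_beam()
  camera <- test_camera()
  sample <- calibrate_amplitude(map, sample_ink(), beam, camera,
                                location = c(800, 800), tau_on = tau_on,
                                target_dT = target_dT)
  list(map = map, sample = sample, beam = beam, camera = camera,
       location = c(800, 800), tau_on = tau_on)
}

.scene_cache <- new.env(parent = emptyenv())

# Six absorbing disks centered on selected scan pixels of a 16 x 8 grid
# with 60 um pixels: exactly one illumination event lands on each disk,
# and no other event comes within beam reach of any disk.
disk_scene <- function(tau_on = 0.3, target_dT = 1.5) {
  key <- sprintf("scene_%g_%g", tau_on, target_dT)
  if (!is.null(.scene_cache[[key]])) return(.scene_cache[[key]])
  proto <- scan_protocol(16, 8, 60, c(8, 4), tau_on = tau_on)
  sched <- build_schedule(proto)
  pick <- data.frame(i = c(2, 6, 10, 14, 4, 12), j = c(1, 3, 5, 1, 6, 3))
  cx <- (pick$i + 0.5) * 60
  cy <- (pick$j + 0.5) * 60
  vals <- matrix(0, nrow = 8 * 60 / 5, ncol = 16 * 60 / 5)
  xs <- (seq_len(ncol(vals)) - 0.5) * 5
  ys <- (seq_len(nrow(vals)) - 0.5) * 5
  for (k in seq_len(6)) {
    vals[outer((ys - cy[k])^2, (xs - cx[k])^2, `+`) <= 25^2] <- 1
  }
  map <- absorber_map(vals, 5, centers = data.frame(x = cx, y = cy))
  beam <- test_beam()
  camera <- camera_model(format = c(8, 6))
  sample <- calibrate_amplitude(map, sample_ink(), beam, camera,
                                c(cx[1], cy[1]), tau_on, target_dT)
  on_disk <- vapply(seq_len(nrow(sched)), function(e) {
    ix <- ceiling(sched$x0[e] / map$pitch)
    iy <- ceiling(sched$y0[e] / map$pitch)
    map$values[iy, ix] > 0
  }, logical(1))
  sc <- list(map = map, sample = sample, beam = beam, camera = camera,
             protocol = proto, schedule = sched, on_disk = on_disk)
  .scene_cache[[key]] <- sc
  sc
}

# Cached rendered stacks of the disk scene (one per noise mode / seed).
disk_stack <- function(noise = "none", seed = NULL) {
  key <- sprintf("stack_%s_%s", noise, seed %||% "NA")
  if (!is.null(.scene_cache[[key]])) return(.scene_cache[[key]])
  sc <- disk_scene()
  st <- render_stack(sc$map, sc$sample, sc$beam, sc$schedule, sc$camera,
                     noise = noise, seed = seed)
  .scene_cache[[key]] <- st
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Event positions in map-absorptance terms: does the pulse center sit on
# an absorbing cell?
events_on_absorber <- function(schedule, map) {
  vapply(seq_len(nrow(schedule)), function(e) {
    ix <- ceiling((schedule$x0[e] - map$origin[1]) / map$pitch)
    iy <- ceiling((schedule$y0[e] - map$origin[2]) / map$pitch)
    ix >= 1 && ix <= ncol(map$values) && iy >= 1 && iy <= nrow(map$values) &&
      map$values[iy, ix] > 0
  }, logical(1))
}

quiet_detect <- function(...) suppressWarnings(detect_stack_events(...))

# photon number implied by a repeatability summary (first listed model)
infer_photons_for_test <- function(rep_result, camera, sample, model = "two_step") {
  s <- rep_result$summary[rep_result$summary$model == model, ]
  thermoloc:::infer_n_photons(s$dTmax, s$zeta2, camera, sample)
}
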