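STEFAN_BOLTZMANN <- 5.67e-8   # W m^-2 K^-4
FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Thermal camera model
#'
#' Far-infrared microbolometer camera observing the sample plane.
#' `netd` is the noise-equivalent temperature difference (per-pixel
#' Gaussian noise std in `netd` noise mode); `psf_fwhm` the optical blur
#' of the collecting lens at thermal wavelengths; `photon_gain` converts
#' excess radiance to detected photons per pixel per frame, and
#' `background` is the background photon count entering the shot-noise
#' model and the localization-precision law.
#'
#' @param pixel_size pixel size on the sample plane, micrometres.
#' @param format sensor format `(n_cols, n_rows)`.
#' @param f_rate frame rate, Hz.
#' @param netd temperature sensitivity, degrees Celsius.
#' @param psf_fwhm optical PSF FWHM on the sample plane, micrometres
#'   (0 disables blurring).
#' @param photon_gain detected photons per (W m^-2) of excess radiance
#'   per pixel per frame.
#' @param background background photons per pixel per frame.
#' @param distance camera-to-sample distance, centimetres (metadata).
#' @param fov field of view, degrees (metadata).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(pixel_size = 400, format = c(320, 240), f_rate = 30,
                         netd = 0.1, psf_fwhm = 345, photon_gain = 11.4,
                         background = 2, distance = 30, fov = c(25, 19)) {
  .assert(pixel_size > 0 && f_rate > 0, "`pixel_size` and `f_rate` must be > 0")
  .assert(netd >= 0 && psf_fwhm >= 0 && background >= 0 && photon_gain > 0,
          "noise parameters must be non-negative (photon_gain > 0)")
  .assert(length(format) == 2 && all(format >= 1), "`format` must be (n_cols, n_rows)")
  structure(list(pixel_size = pixel_size, format = as.integer(format),
                 f_rate = f_rate, netd = netd, psf_fwhm = psf_fwhm,
                 photon_gain = photon_gain, background = background,
                 distance = distance, fov = fov),
            class = "camera_model")
}

#' Uncooled 320 x 240 camera preset
#'
#' The default imaging geometry used throughout: 320 x 240 format,
#' ~400 um pixels on the sample plane, 30 Hz, 0.1 degC sensitivity and a
#' 345 um diffraction-limited PSF.
#'
#' @param ... overrides passed on to [camera_model()].
#' @return A `camera_model`.
#' @export
camera_flir_e40 <- function(...) {
  do.call(camera_model, utils::modifyList(list(), list(...)))
}

# photons per degC per pixel: photon_gain * d(radiance)/dT at T0 (linearized)
photons_per_degC <- function(camera, sample) {
  t0k <- sample$T0 + 273.15
  camera$photon_gain * 4 * sample$emissivity * STEFAN_BOLTZMANN * t0k^3
}

#' Gray-body radiance
#'
#' Stefan-Boltzmann law for a gray body: `R = emissivity * sigma * T^4`
#' with `T` in kelvin.
#'
#' @param temp_c temperature, degrees Celsius.
#' @param emissivity dimensionless, in \[0, 1\].
#' @return Radiance, W m^-2.
#' @export
radiance <- function(temp_c, emissivity) {
  .assert(all(emissivity >= 0 & emissivity <= 1), "`emissivity` must be in [0, 1]")
  if (any(temp_c <= -273.15)) stop("temperature below absolute zero", call. = FALSE)
  emissivity * STEFAN_BOLTZMANN * (temp_c + 273.15)^4
}

#' Fractional error of the linearized photon-number law
#'
#' The detected photon number is proportional to the excess radiance
#' `(T0 + dT)^4 - T0^4`, commonly linearized as `4 T0^3 dT`. This returns
#' the fractional underestimate of the linearized form,
#' `1 - 4 T0^3 dT / ((T0 + dT)^4 - T0^4)`.
#'
#' @param T0_k baseline temperature, kelvin.
#' @param dT_k temperature increment, kelvin.
#' @return Fractional underestimate (dimensionless, >= 0).
#' @export
photon_linearization_error <- function(T0_k, dT_k) {
  .assert(all(T0_k > 0), "`T0_k` must be > 0")
  .assert(all(dT_k >= 0), "`dT_k` must be >= 0")
  ifelse(dT_k == 0, 0,
         1 - 4 * T0_k^3 * dT_k / ((T0_k + dT_k)^4 - T0_k^4))
}

# --- forward-model internals -------------------------------------------------

# Discretized heat source for one illumination event: absorber cells under
# the beam, weighted by the Gaussian intensity profile. Cells where the
# beam intensity is below `cutoff` of its peak are dropped.
event_source <- function(map, beam, x0, y0, cutoff = 1e-4) {
  ax <- map_axes(map)
  r_max <- beam$w0 * sqrt(log(1 / cutoff) / 2)
  ix <- which(ax$x >= x0 - r_max & ax$x <= x0 + r_max)
  iy <- which(ax$y >= y0 - r_max & ax$y <= y0 + r_max)
  if (length(ix) == 0 || length(iy) == 0) return(NULL)
  sub <- map$values[iy, ix, drop = FALSE]
  if (all(sub == 0)) return(NULL)
  wx <- exp(-2 * (ax$x[ix] - x0)^2 / beam$w0^2)
  wy <- exp(-2 * (ax$y[iy] - y0)^2 / beam$w0^2)
  # Q indexed [x-cell, y-cell]; integrated source strength per cell
  q <- t(sub * outer(wy, wx)) * map$pitch^2
  list(sx = ax$x[ix], sy = ax$y[iy], q = q)
}

# Age beyond which one event's residual temperature at the camera plane is
# bounded below tol_abs (degC). The bound assumes unit absorptance: the
# event deposits at most A * pi w0^2 / 2 * tau_on (degC um^2); an increment
# of age a has peak surface density 1 / (2 pi (w0^2/4 + 2 D a + sig_psf^2))
# and Newton-cooling factor exp(-a / tau_d).
event_age_max <- function(sample, beam, tau_on, sig_psf2 = 0, tol_abs = 1e-3) {
  if (sample$A <= 0) return(0)
  v0 <- beam$w0^2 / 4 + sig_psf2
  q <- sample$A * (pi * beam$w0^2 / 2) * tau_on
  bound <- function(a) {
    q * exp(-a / sample$tau_d) / (2 * pi * (v0 + 2 * sample$diffusivity * a)) - tol_abs
  }
  if (bound(0) <= 0) return(0)
  hi <- sample$tau_d * log(q / (2 * pi * v0 * tol_abs))
  while (bound(hi) > 0) hi <- hi * 2
  uniroot(bound, c(0, hi))$root
}

# Trapezoid nodes over the emission interval [0, min(t_rel, tau_on)].
quad_nodes <- function(t_rel, tau_on, step) {
  upper <- min(t_rel, tau_on)
  n <- max(2L, ceiling(upper / step) + 1L)
  u <- seq(0, upper, length.out = n)
  w <- rep(upper / (n - 1), n)
  w[c(1, n)] <- w[c(1, n)] / 2
  list(u = u, w = w)
}

#' Laser-induced temperature field
#'
#' Evaluates the temperature increment induced by a sequence of laser
#' pulses at arbitrary lab-frame positions and times. Each pulse
#' deposits heat at rate `A * absorptance(r) * exp(-2 |r - r0|^2 / w0^2)`
#' over its duration; every deposited increment then spreads with the 2D
#' heat kernel (variance `2 D age` per axis) and loses amplitude by
#' Newton cooling `exp(-age / tau_d)`. The emission-time integral is
#' evaluated by fixed-step trapezoid quadrature with step
#' `<= tau_on / 50`.
#'
#' @param map an [absorber_map].
#' @param sample a [sample_model].
#' @param beam a [beam_model].
#' @param schedule an `illumination_schedule`, or any data frame with
#'   columns `x0`, `y0`, `t0`, `duration`.
#' @param points numeric matrix (n x 2) of query positions, micrometres.
#' @param times numeric vector of query times, seconds.
#' @param quad_step quadrature step, seconds (default `tau_on / 50`).
#' @return Matrix of temperature increments (degC), `n_points` rows by
#'   `length(times)` columns. Query times before the first pulse give 0.
#' @export
temperature_field <- function(map, sample, beam, schedule, points, times,
                              quad_step = NULL) {
  .assert(inherits(map, "absorber_map"), "`map` must be an absorber_map")
  points <- matrix(as.numeric(points), ncol = 2)
  out <- matrix(0, nrow(points), length(times))
  if (nrow(schedule) == 0 || sample$A == 0) return(out)
  ax <- map_axes(map)
  nearest_abs <- function(px, py) {
    ix <- pmin(pmax(floor((px - map$origin[1]) / map$pitch) + 1, 1), ncol(map$values))
    iy <- pmin(pmax(floor((py - map$origin[2]) / map$pitch) + 1, 1), nrow(map$values))
    map$values[cbind(iy, ix)]
  }
  for (e in seq_len(nrow(schedule))) {
    tau_on <- schedule$duration[e]
    step <- quad_step %||% (tau_on / 50)
    src <- NULL
    rel <- times - schedule$t0[e]
    active <- which(rel > 0)
    if (length(active) == 0) next
    for (kt in active) {
      qn <- quad_nodes(rel[kt], tau_on, step)
      age <- rel[kt] - qn$u
      wt <- sample$A * qn$w * exp(-age / sample$tau_d)
      s2 <- 2 * sample$diffusivity * age
      for (k in seq_along(age)) {
        if (s2[k] < (map$pitch / 2)^2) {
          # effectively unspread: local product of map and beam profile
          d2 <- (points[, 1] - schedule$x0[e])^2 + (points[, 2] - schedule$y0[e])^2
          out[, kt] <- out[, kt] + wt[k] * nearest_abs(points[, 1], points[, 2]) *
            exp(-2 * d2 / beam$w0^2)
        } else {
          if (is.null(src)) {
            src <- event_source(map, beam, schedule$x0[e], schedule$y0[e])
            if (is.null(src)) break
          }
          kx <- exp(-outer(points[, 1], src$sx, `-`)^2 / (2 * s2[k]))
          ky <- exp(-outer(points[, 2], src$sy, `-`)^2 / (2 * s2[k]))
          out[, kt] <- out[, kt] +
            wt[k] / (2 * pi * s2[k]) * rowSums((kx %*% src$q) * ky)
        }
      }
    }
  }
  out
}

# Render clean (noise-free) camera frames of the temperature increment at
# the given times. The camera applies a Gaussian optical PSF and averages
# the field over each pixel footprint; both steps are carried out
# analytically (each source cell is a point source whose blurred image is
# a Gaussian, whose pixel-box average is a product of error functions).
render_frames <- function(map, sample, beam, schedule, camera, times,
                          origin = NULL, tol_abs = 1e-3, quad_step = NULL) {
  n_col <- camera$format[1]; n_row <- camera$format[2]
  a_px <- camera$pixel_size
  if (is.null(origin)) {
    ctr <- map$origin + c(ncol(map$values), nrow(map$values)) * map$pitch / 2
    origin <- ctr - c(n_col, n_row) * a_px / 2
  }
  frames <- array(0, dim = c(n_row, n_col, length(times)))
  if (nrow(schedule) == 0 || sample$A == 0) {
    return(list(frames = frames, origin = origin))
  }
  sig_psf2 <- (camera$psf_fwhm * FWHM_TO_SIGMA)^2
  edges_x <- origin[1] + (0:n_col) * a_px
  edges_y <- origin[2] + (0:n_row) * a_px
  a_max <- event_age_max(sample, beam, max(schedule$duration), sig_psf2, tol_abs)
  for (e in seq_len(nrow(schedule))) {
    tau_on <- schedule$duration[e]
    step <- quad_step %||% (tau_on / 50)
    rel <- times - schedule$t0[e]
    active <- which(rel > 0 & rel <= tau_on + a_max)
    if (length(active) == 0) next
    src <- event_source(map, beam, schedule$x0[e], schedule$y0[e])
    if (is.null(src)) next
    for (kt in active) {
      # the integrand is smooth in the emission time once all contributing
      # increments are old (ages >> tau_on), so decayed events need far
      # fewer trapezoid nodes than the in-pulse fine step
      step_kt <- if (rel[kt] <= tau_on + 0.5) step else tau_on / 8
      qn <- quad_nodes(rel[kt], tau_on, step_kt)
      age <- rel[kt] - qn$u
      wt <- sample$A * qn$w * exp(-age / sample$tau_d)
      s <- sqrt(pmax(2 * sample$diffusivity * age + sig_psf2, 1e-12))
      smax <- max(s)
      ix <- which(edges_x[-1] > min(src$sx) - 5 * smax &
                  edges_x[-(n_col + 1)] < max(src$sx) + 5 * smax)
      iy <- which(edges_y[-1] > min(src$sy) - 5 * smax &
                  edges_y[-(n_row + 1)] < max(src$sy) + 5 * smax)
      if (length(ix) == 0 || length(iy) == 0) next
      nk <- length(s)
      # stacked per-node box-average factors along x and y
      lox <- rep(edges_x[ix], nk); hix <- rep(edges_x[ix + 1], nk)
      sx_rep <- rep(s, each = length(ix))
      ex <- (pnorm(outer(hix, src$sx, `-`) / sx_rep) -
             pnorm(outer(lox, src$sx, `-`) / sx_rep)) / a_px
      loy <- rep(edges_y[iy], nk); hiy <- rep(edges_y[iy + 1], nk)
      sy_rep <- rep(s, each = length(iy))
      ey <- (pnorm(outer(hiy, src$sy, `-`) / sy_rep) -
             pnorm(outer(loy, src$sy, `-`) / sy_rep)) / a_px
      bx <- ex %*% src$q                      # (nk*nax) x ncy
      add <- matrix(0, length(iy), length(ix))
      for (k in seq_len(nk)) {
        rx <- ((k - 1) * length(ix) + 1):(k * length(ix))
        ry <- ((k - 1) * length(iy) + 1):(k * length(iy))
        add <- add + wt[k] * ey[ry, , drop = FALSE] %*% t(bx[rx, , drop = FALSE])
      }
      frames[iy, ix, kt] <- frames[iy, ix, kt] + add
    }
  }
  list(frames = frames, origin = origin)
}

#' Thermal camera stack
#'
#' Container for a time-stamped sequence of temperature frames.
#'
#' @param frames 3D array `[row, col, frame]` of temperatures, degC.
#' @param f_rate frame rate, Hz; frame `k` (1-based) is stamped
#'   `(k - 1) / f_rate` seconds.
#' @param pixel_size camera pixel size on the sample plane, micrometres.
#' @param origin lab-frame position of the corner of pixel (1, 1),
#'   micrometres.
#' @param T0 baseline temperature, degC.
#' @param camera optional [camera_model] the stack was rendered with.
#' @return An object of class `thermal_stack`.
#' @export
thermal_stack <- function(frames, f_rate, pixel_size, origin = c(0, 0),
                          T0 = NA_real_, camera = NULL) {
  .assert(length(dim(frames)) == 3, "`frames` must be a 3D array [row, col, frame]")
  .assert(f_rate > 0 && pixel_size > 0, "`f_rate` and `pixel_size` must be > 0")
  structure(list(frames = frames, f_rate = f_rate, pixel_size = pixel_size,
                 origin = as.numeric(origin), T0 = T0, camera = camera),
            class = "thermal_stack")
}

#' @export
print.thermal_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("thermal_stack: %d frames of %d x %d px (%.3g um) at %g Hz, T0 = %.3g degC\n",
              d[3], d[1], d[2], x$pixel_size, x$f_rate, x$T0))
  invisible(x)
}

#' @export
dim.thermal_stack <- function(x) dim(x$frames)

stack_timestamps <- function(stack) (seq_len(dim(stack$frames)[3]) - 1) / stack$f_rate

#' Render a noisy thermo-camera stack
#'
#' Runs the forward model over the full illumination schedule and samples
#' it with the camera: at each frame time the clean temperature-increment
#' field is blurred by the optical PSF, box-averaged over each pixel
#' footprint and added to the baseline `T0`. Noise modes:
#' \describe{
#'   \item{`netd`}{adds i.i.d. Gaussian noise with std `camera$netd`;}
#'   \item{`photon`}{converts each pixel to expected photon counts
#'     `b + photon_gain * 4 eps sigma T0^3 * dT` (linearized gray-body
#'     excess radiance), draws a Poisson sample and maps it back to
#'     temperature, so localization error scales with photon number;}
#'   \item{`none`}{returns the clean stack.}
#' }
#'
#' @inheritParams temperature_field
#' @param camera a [camera_model].
#' @param duration stack duration, seconds (default: schedule end plus
#'   the thermal decay tail). A duration shorter than the schedule
#'   truncates the stack with a warning.
#' @param noise one of `"netd"`, `"photon"`, `"none"`.
#' @param seed integer seed; mandatory for the stochastic noise modes.
#' @param origin camera origin override, micrometres (default: camera
#'   field of view centered on the absorber map).
#' @return A [thermal_stack()].
#' @export
render_stack <- function(map, sample, beam, schedule, camera,
                         duration = NULL, noise = c("netd", "photon", "none"),
                         seed = NULL, origin = NULL, quad_step = NULL) {
  noise <- match.arg(noise)
  sched_end <- if (nrow(schedule)) max(schedule$t0 + schedule$duration) else 0
  if (is.null(duration)) {
    duration <- sched_end +
      event_age_max(sample, beam, if (nrow(schedule)) max(schedule$duration) else 1,
                    (camera$psf_fwhm * FWHM_TO_SIGMA)^2)
  } else if (duration < sched_end) {
    warning("`duration` is shorter than the illumination schedule; the stack is truncated")
  }
  times <- seq(0, duration, by = 1 / camera$f_rate)
  rf <- render_frames(map, sample, beam, schedule, camera, times,
                      origin = origin, quad_step = quad_step)
  frames <- rf$frames + sample$T0
  if (noise != "none") {
    .assert(!is.null(seed), "a `seed` is required for stochastic noise modes")
    set.seed(as.integer(seed))
    frames <- add_camera_noise(frames, noise, camera, sample)
  }
  thermal_stack(frames, f_rate = camera$f_rate, pixel_size = camera$pixel_size,
                origin = rf$origin, T0 = sample$T0, camera = camera)
}

# Apply camera noise to absolute-temperature frames (any numeric array).
# Assumes the RNG state has been seeded by the caller.
add_camera_noise <- function(frames, noise, camera, sample) {
  if (noise == "netd") {
    frames + array(rnorm(length(frames), 0, camera$netd), dim = dim(frames))
  } else if (noise == "photon") {
    gain <- photons_per_degC(camera, sample)
    n_exp <- camera$background + gain * pmax(frames - sample$T0, 0)
    counts <- array(rpois(length(n_exp), n_exp), dim = dim(frames))
    sample$T0 + (counts - camera$background) / gain
  } else {
    frames
  }
}
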