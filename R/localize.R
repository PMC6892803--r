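# Gaussian-surface models over a pixel grid. x: column centers, y: row
# centers (micrometres); surfaces are evaluated as outer(y, x) matrices.

surface_symmetric <- function(x, y, xc, yc, zx2, zy2 = zx2, lx = 0, ly = 0,
                              amp = 1, off = 0) {
  gx <- exp(-(x - xc)^2 / (2 * zx2))
  gy <- exp(-(y - yc)^2 / (2 * zy2))
  if (lx != 0) gx <- gx * (1 + .erf(lx * (x - xc) / sqrt(2 * zx2)))
  if (ly != 0) gy <- gy * (1 + .erf(ly * (y - yc) / sqrt(2 * zy2)))
  off + amp * outer(gy, gx)
}

.lm_fit <- function(par0, resid_fun, lower, upper) {
  tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par0, fn = resid_fun, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ptol = 1e-10, ftol = 1e-10))),
    error = function(e) NULL)
}

new_localization <- function(x_c = NA_real_, y_c = NA_real_, zeta2 = NA_real_,
                             dTmax = NA_real_, offset = NA_real_,
                             model = NA_character_, chi2red = NA_real_,
                             converged = FALSE, extra = NULL) {
  structure(c(list(x_c = x_c, y_c = y_c, zeta2 = zeta2, dTmax = dTmax,
                   offset = offset, sigma_x = NA_real_, sigma_y = NA_real_,
                   n_photons = NA_real_, model = model, chi2red = chi2red,
                   converged = converged), extra),
            class = "localization")
}

#' @export
print.localization <- function(x, ...) {
  cat(sprintf("localization [%s]: center (%.2f, %.2f) um, dTmax %.3f degC, zeta %.1f um%s\n",
              x$model, x$x_c, x$y_c, x$dTmax, sqrt(x$zeta2),
              if (is.finite(x$sigma_x)) sprintf(", sigma %.1f um", x$sigma_x) else ""))
  invisible(x)
}

#' Two-step symmetric Gaussian peak fit
#'
#' The center-scatter-minimizing fit used for all reconstructions: step 1
#' fits a symmetric 2D Gaussian with *fixed* variance `zeta0_sq` (free
#' center, amplitude, offset) to pin down the peak coordinates; step 2
#' fixes the center and frees the variance, amplitude and offset to
#' recover the spot variance `zeta^2` and the amplitude `dTmax`.
#'
#' @param z numeric matrix of temperatures `[row, col]`, degC.
#' @param x,y pixel-center coordinates of the columns / rows of `z`,
#'   micrometres.
#' @param zeta0_sq fixed spatial variance for step 1, um^2 (see
#'   [default_zeta0_sq()]).
#' @return A `localization` object; `converged = FALSE` flags a failed
#'   fit (non-convergence or non-positive amplitude).
#' @export
fit_peak_two_step <- function(z, x, y, zeta0_sq) {
  .assert(zeta0_sq > 0, "`zeta0_sq` must be > 0")
  .assert(nrow(z) == length(y) && ncol(z) == length(x), "z / x / y dimensions disagree")
  imax <- which(z == max(z), arr.ind = TRUE)[1, ]
  off0 <- median(z)
  par0 <- c(xc = x[imax[2]], yc = y[imax[1]], amp = max(z) - off0, off = off0)
  r1 <- function(p) as.vector(z - surface_symmetric(x, y, p[1], p[2], zeta0_sq,
                                                    amp = p[3], off = p[4]))
  f1 <- .lm_fit(par0, r1,
                lower = c(min(x), min(y), 0, -Inf),
                upper = c(max(x), max(y), Inf, Inf))
  if (is.null(f1) || !(f1$info %in% 1:5) || f1$par[3] <= 0) {
    return(new_localization(model = "symmetric_two_step"))
  }
  xc <- unname(f1$par[1]); yc <- unname(f1$par[2])
  par2 <- c(zeta2 = zeta0_sq, amp = f1$par[3], off = f1$par[4])
  r2 <- function(p) as.vector(z - surface_symmetric(x, y, xc, yc, p[1],
                                                    amp = p[2], off = p[3]))
  span2 <- (max(max(x) - min(x), max(y) - min(y)))^2
  f2 <- .lm_fit(par2, r2, lower = c(zeta0_sq / 1e4, 0, -Inf),
                upper = c(4 * span2, Inf, Inf))
  if (is.null(f2) || !(f2$info %in% 1:5) || f2$par[2] <= 0) {
    return(new_localization(model = "symmetric_two_step"))
  }
  res <- r2(f2$par)
  p2 <- unname(f2$par)
  new_localization(x_c = xc, y_c = yc, zeta2 = p2[1], dTmax = p2[2],
                   offset = p2[3], model = "symmetric_two_step",
                   chi2red = sum(res^2) / (length(res) - 4), converged = TRUE)
}

#' Single-step Gaussian peak fits
#'
#' One-shot nonlinear least squares of a 2D peak surface: `symmetric`
#' (one variance), `asymmetric` (separate x / y variances) or `skewed`
#' (asymmetric multiplied per axis by a skew-normal factor
#' `1 + erf(lambda (coord - center) / sqrt(2) zeta)` with free lambda).
#' Used by the fit-selection comparison; the two-step symmetric fit
#' ([fit_peak_two_step()]) is the default for reconstruction.
#'
#' @inheritParams fit_peak_two_step
#' @param model one of `"symmetric"`, `"asymmetric"`, `"skewed"`.
#' @param zeta0_sq initial spot variance, um^2.
#' @return A `localization` object. For the asymmetric and skewed models
#'   `zeta2` is the geometric mean of the per-axis variances and the
#'   per-axis parameters are reported in `$extra`.
#' @export
fit_peak_single <- function(z, x, y, model = c("symmetric", "asymmetric", "skewed"),
                            zeta0_sq) {
  model <- match.arg(model)
  .assert(zeta0_sq > 0, "`zeta0_sq` must be > 0")
  imax <- which(z == max(z), arr.ind = TRUE)[1, ]
  off0 <- median(z)
  span2 <- (max(max(x) - min(x), max(y) - min(y)))^2
  base0 <- c(xc = x[imax[2]], yc = y[imax[1]])
  lo_c <- c(min(x), min(y)); hi_c <- c(max(x), max(y))
  zlo <- zeta0_sq / 1e4; zhi <- 4 * span2
  if (model == "symmetric") {
    par0 <- c(base0, z2 = zeta0_sq, amp = max(z) - off0, off = off0)
    rf <- function(p) as.vector(z - surface_symmetric(x, y, p[1], p[2], p[3],
                                                      amp = p[4], off = p[5]))
    lower <- c(lo_c, zlo, 0, -Inf); upper <- c(hi_c, zhi, Inf, Inf)
  } else if (model == "asymmetric") {
    par0 <- c(base0, zx2 = zeta0_sq, zy2 = zeta0_sq, amp = max(z) - off0, off = off0)
    rf <- function(p) as.vector(z - surface_symmetric(x, y, p[1], p[2], p[3], p[4],
                                                      amp = p[5], off = p[6]))
    lower <- c(lo_c, zlo, zlo, 0, -Inf); upper <- c(hi_c, zhi, zhi, Inf, Inf)
  } else {
    par0 <- c(base0, zx2 = zeta0_sq, zy2 = zeta0_sq, lx = 0, ly = 0,
              amp = max(z) - off0, off = off0)
    rf <- function(p) as.vector(z - surface_symmetric(x, y, p[1], p[2], p[3], p[4],
                                                      p[5], p[6], p[7], p[8]))
    lower <- c(lo_c, zlo, zlo, -10, -10, 0, -Inf)
    upper <- c(hi_c, zhi, zhi, 10, 10, Inf, Inf)
  }
  ft <- .lm_fit(par0, rf, lower, upper)
  if (is.null(ft) || !(ft$info %in% 1:5)) return(new_localization(model = model))
  p <- unname(ft$par)
  res <- rf(p)
  chi2 <- sum(res^2) / (length(res) - length(p))
  if (model == "symmetric") {
    if (p[4] <= 0) return(new_localization(model = model))
    new_localization(p[1], p[2], p[3], p[4], p[5], model, chi2, TRUE)
  } else if (model == "asymmetric") {
    if (p[5] <= 0) return(new_localization(model = model))
    new_localization(p[1], p[2], sqrt(p[3] * p[4]), p[5], p[6], model, chi2, TRUE,
                     extra = list(zeta_x2 = unname(p[3]), zeta_y2 = unname(p[4])))
  } else {
    if (p[7] <= 0) return(new_localization(model = model))
    surf <- surface_symmetric(x, y, p[1], p[2], p[3], p[4], p[5], p[6], p[7], 0)
    new_localization(p[1], p[2], sqrt(p[3] * p[4]), max(surf), p[8], model, chi2, TRUE,
                     extra = list(zeta_x2 = unname(p[3]), zeta_y2 = unname(p[4]),
                                  lambda_x = unname(p[5]), lambda_y = unname(p[6])))
  }
}

#' Closed-form localization precision
#'
#' Centroid-fit uncertainty of a Gaussian peak sampled on a pixel grid:
#' `sigma = sqrt((zeta^2 + a^2 / 12) / N + 4 sqrt(pi) b^2 zeta^3 / (a N^2))`,
#' where `zeta` is the spot standard deviation, `a` the pixel size, `N`
#' the number of collected signal photons and `b` the background photons
#' per pixel.
#'
#' @param zeta fitted spot standard deviation, micrometres.
#' @param a pixel size, micrometres.
#' @param b background photons per pixel.
#' @param n_photons collected signal photons (> 0).
#' @return Localization uncertainty, micrometres.
#' @export
predict_sigma <- function(zeta, a, b = 0, n_photons) {
  .assert(all(zeta > 0) && a > 0 && all(b >= 0), "invalid inputs")
  if (any(n_photons <= 0)) stop("`n_photons` must be > 0", call. = FALSE)
  sqrt((zeta^2 + a^2 / 12) / n_photons +
         4 * sqrt(pi) * b^2 * zeta^3 / (a * n_photons^2))
}

#' Empirical precision-versus-amplitude law
#'
#' Since the collected photon number is proportional to the temperature
#' increment, the precision law collapses to
#' `sigma = sqrt(alpha / dT + beta / dT^2)`; with calibrated `alpha` and
#' `beta` this extrapolates the localization uncertainty to any measured
#' amplitude.
#'
#' @param alpha degC um^2 coefficient (shot-noise term).
#' @param beta degC^2 um^2 coefficient (background term).
#' @param dT temperature increment(s), degC (> 0).
#' @return Localization uncertainty, micrometres.
#' @export
sigma_vs_deltaT <- function(alpha, beta, dT) {
  .assert(alpha >= 0 && beta >= 0, "`alpha` and `beta` must be >= 0")
  if (any(dT <= 0)) stop("`dT` must be > 0", call. = FALSE)
  sqrt(alpha / dT + beta / dT^2)
}

#' Calibrate the precision-versus-amplitude law
#'
#' Least-squares fit of `sigma^2 = alpha / dT + beta / dT^2` to measured
#' (amplitude, uncertainty) pairs, with the coefficients constrained to
#' be non-negative (a negative unconstrained estimate is clamped to zero
#' and the other coefficient refit).
#'
#' @param dT measured amplitudes, degC.
#' @param sigma measured localization uncertainties, micrometres.
#' @return List with `alpha`, `beta`, their standard errors and the
#'   fitted `sigma` values.
#' @export
calibrate_alpha_beta <- function(dT, sigma) {
  .assert(length(dT) == length(sigma) && length(dT) >= 4,
          "need at least 4 (dT, sigma) pairs")
  if (max(dT) / min(dT) < 2) {
    stop("degenerate design: amplitudes must span at least a 2-fold range",
         call. = FALSE)
  }
  y <- sigma^2; x1 <- 1 / dT; x2 <- 1 / dT^2
  fit <- lm(y ~ 0 + x1 + x2)
  cf <- coef(fit)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))  # warns on perfect fits
  alpha <- cf[["x1"]]; beta <- cf[["x2"]]
  se_alpha <- se[["x1"]]; se_beta <- se[["x2"]]
  if (alpha < 0 || beta < 0) {
    if (alpha >= beta) {        # keep the dominant non-negative term
      fit <- lm(y ~ 0 + x1)
      alpha <- max(0, coef(fit)[["x1"]]); beta <- 0
      se_alpha <- suppressWarnings(sqrt(diag(stats::vcov(fit))))[["x1"]]; se_beta <- 0
    } else {
      fit <- lm(y ~ 0 + x2)
      beta <- max(0, coef(fit)[["x2"]]); alpha <- 0
      se_beta <- suppressWarnings(sqrt(diag(stats::vcov(fit))))[["x2"]]; se_alpha <- 0
    }
  }
  list(alpha = alpha, beta = beta, se_alpha = se_alpha, se_beta = se_beta,
       fitted_sigma = sqrt(pmax(alpha / dT + beta / dT^2, 0)))
}

#' Default fixed variance for the two-step fit
#'
#' The clean forward-model spot variance at the end of the pulse: beam
#' variance `w0^2 / 4`, diffusive broadening `2 D tau_on` and optical
#' blur `sigma_psf^2`.
#'
#' @param sample a [sample_model].
#' @param beam a [beam_model].
#' @param camera a [camera_model].
#' @param tau_on activation time, seconds.
#' @return Variance, um^2.
#' @export
default_zeta0_sq <- function(sample, beam, camera, tau_on) {
  beam$w0^2 / 4 + 2 * sample$diffusivity * tau_on +
    (camera$psf_fwhm * FWHM_TO_SIGMA)^2
}

# Infer the collected signal photons from a fitted amplitude: per-pixel
# photons-per-degC times the effective number of spot pixels 2 pi zeta^2 / a^2.
infer_n_photons <- function(dTmax, zeta2, camera, sample) {
  photons_per_degC(camera, sample) * dTmax * 2 * pi * zeta2 / camera$pixel_size^2
}

# Attach the closed-form (camera + sample) or empirical (alpha/beta)
# localization uncertainty to a localization.
attach_sigma <- function(loc, camera = NULL, sample = NULL, uncertainty = NULL) {
  if (!isTRUE(loc$converged)) return(loc)
  if (!is.null(uncertainty)) {
    s <- sigma_vs_deltaT(uncertainty[[1]], uncertainty[[2]], loc$dTmax)
  } else if (!is.null(camera) && !is.null(sample)) {
    n <- infer_n_photons(loc$dTmax, loc$zeta2, camera, sample)
    loc$n_photons <- n
    s <- predict_sigma(sqrt(loc$zeta2), camera$pixel_size, camera$background, n)
  } else {
    return(loc)
  }
  loc$sigma_x <- s; loc$sigma_y <- s
  loc
}

#' Localize detected events on camera frames
#'
#' For each detected event, extracts a fit window around the event pixel
#' from the event's frame (default 11 x 11 camera pixels, clipped at the
#' frame edges; the fit proceeds if at least 7 pixels remain per axis)
#' and fits the chosen peak model. Centers are returned in lab-frame
#' micrometres. When the stack carries its camera model and `sample` is
#' supplied, the closed-form precision law is attached; otherwise pass
#' `uncertainty = c(alpha, beta)` to use the empirical law.
#'
#' @param stack a [thermal_stack()].
#' @param events data frame from [detect_stack_events()].
#' @param zeta0_sq fixed step-1 variance, um^2.
#' @param model `"two_step"` (default) or a [fit_peak_single()] model.
#' @param fit_roi fit window side, camera pixels.
#' @param sample optional [sample_model] for photon-number inference.
#' @param uncertainty optional `c(alpha, beta)` empirical law.
#' @return Data frame with one row per successfully fitted event
#'   (`x_c`, `y_c`, `sigma_x`, `sigma_y`, `dTmax`, `zeta2`, `offset`,
#'   `model`, `chi2red`, `frame`, `time`); events dropped by fit failure
#'   or undersized windows are counted in attribute `n_dropped`.
#' @export
localize_events <- function(stack, events, zeta0_sq,
                            model = c("two_step", "symmetric", "asymmetric", "skewed"),
                            fit_roi = 11, sample = NULL, uncertainty = NULL) {
  model <- match.arg(model)
  .assert(inherits(stack, "thermal_stack"), "`stack` must be a thermal_stack")
  d <- dim(stack$frames)
  half <- floor(fit_roi / 2)
  xs <- stack$origin[1] + (seq_len(d[2]) - 0.5) * stack$pixel_size
  ys <- stack$origin[2] + (seq_len(d[1]) - 0.5) * stack$pixel_size
  out <- list(); dropped <- 0L
  for (e in seq_len(nrow(events))) {
    cols <- max(1, events$col[e] - half):min(d[2], events$col[e] + half)
    rows <- max(1, events$row[e] - half):min(d[1], events$row[e] + half)
    if (length(cols) < 7 || length(rows) < 7) { dropped <- dropped + 1L; next }
    z <- stack$frames[rows, cols, events$frame[e]]
    loc <- if (model == "two_step") {
      fit_peak_two_step(z, xs[cols], ys[rows], zeta0_sq)
    } else {
      fit_peak_single(z, xs[cols], ys[rows], model, zeta0_sq)
    }
    if (!loc$converged) { dropped <- dropped + 1L; next }
    loc <- attach_sigma(loc, stack$camera, sample, uncertainty)
    out[[length(out) + 1]] <- data.frame(
      x_c = loc$x_c, y_c = loc$y_c, sigma_x = loc$sigma_x, sigma_y = loc$sigma_y,
      dTmax = loc$dTmax, zeta2 = loc$zeta2, offset = loc$offset,
      model = loc$model, chi2red = loc$chi2red,
      frame = events$frame[e], time = events$time[e])
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(x_c = numeric(0), y_c = numeric(0), sigma_x = numeric(0),
               sigma_y = numeric(0), dTmax = numeric(0), zeta2 = numeric(0),
               offset = numeric(0), model = character(0), chi2red = numeric(0),
               frame = integer(0), time = numeric(0))
  attr(res, "n_dropped") <- dropped
  res
}

#' Rescale the heating amplitude to hit a target camera amplitude
#'
#' Renders one clean pulse at the given location, fits it, and linearly
#' rescales the sample's heating amplitude `A` so that the fitted camera
#' amplitude equals `target_dT` (the rendered amplitude is exactly linear
#' in `A`). Mirrors the experimental practice of adjusting laser power or
#' pulse length to reach a desired signal level.
#'
#' @inheritParams run_repeatability
#' @param target_dT desired fitted amplitude, degC.
#' @return The `sample_model` with rescaled `A`.
#' @export
calibrate_amplitude <- function(map, sample, beam, camera, location, tau_on,
                                target_dT, zeta0_sq = NULL) {
  zeta0_sq <- zeta0_sq %||% default_zeta0_sq(sample, beam, camera, tau_on)
  sched <- data.frame(x0 = location[1], y0 = location[2], t0 = 0, duration = tau_on)
  rf <- render_frames(map, sample, beam, sched, camera, times = tau_on)
  z <- rf$frames[, , 1]
  d <- dim(z)
  xs <- rf$origin[1] + (seq_len(d[2]) - 0.5) * camera$pixel_size
  ys <- rf$origin[2] + (seq_len(d[1]) - 0.5) * camera$pixel_size
  loc <- fit_peak_two_step(z, xs, ys, zeta0_sq)
  .assert(loc$converged && loc$dTmax > 0,
          "reference fit failed; is the beam on an absorbing region?")
  sample$A <- sample$A * target_dT / loc$dTmax
  sample
}

#' Localization repeatability at a fixed location
#'
#' Simulates `n_pulses` identical, temporally well-separated laser pulses
#' at one location, renders the frame at the end of each pulse with the
#' chosen noise model, localizes every pulse with each requested fit
#' model on the same frames, and summarizes the per-model scatter of the
#' fitted centers -- the empirical localization uncertainty.
#'
#' @param map an [absorber_map].
#' @param sample a [sample_model].
#' @param beam a [beam_model].
#' @param camera a [camera_model].
#' @param location length-2 numeric, pulse center, micrometres.
#' @param n_pulses number of pulses.
#' @param tau_on activation time, seconds.
#' @param seed integer seed for the noise.
#' @param models subset of `c("two_step", "symmetric", "asymmetric", "skewed")`.
#' @param noise `"photon"`, `"netd"` or `"none"`.
#' @param spacing pulse spacing, seconds; the default satisfies the
#'   separation rule. Overlapping pulses (spacing below the thermal decay
#'   window) are an error.
#' @param zeta0_sq step-1 variance, um^2 (default [default_zeta0_sq()]).
#' @param fit_roi fit window side, camera pixels.
#' @return List with `dT_mean` (mean fitted amplitude over models),
#'   `summary` (data frame: model, empirical `sigma_x`, `sigma_y`, mean
#'   `dTmax`, mean `zeta2`, fits converged) and `fits` (per-model data
#'   frames of all localizations).
#' @export
run_repeatability <- function(map, sample, beam, camera, location,
                              n_pulses = 150, tau_on, seed,
                              models = c("two_step", "symmetric", "asymmetric", "skewed"),
                              noise = "photon", spacing = NULL,
                              zeta0_sq = NULL, fit_roi = 11) {
  zeta0_sq <- zeta0_sq %||% default_zeta0_sq(sample, beam, camera, tau_on)
  min_spacing <- tau_on +
    event_age_max(sample, beam, tau_on, (camera$psf_fwhm * FWHM_TO_SIGMA)^2)
  ms <- min_separation(sample, tau_on, beam)
  spacing <- spacing %||% max(ms$dt_min, min_spacing * 1.01)
  if (spacing < min_spacing) {
    stop("pulses overlap: spacing must exceed tau_on plus the thermal decay window",
         call. = FALSE)
  }
  sched <- data.frame(x0 = location[1], y0 = location[2],
                      t0 = (seq_len(n_pulses) - 1) * spacing, duration = tau_on)
  fit_times <- sched$t0 + tau_on
  rf <- render_frames(map, sample, beam, sched, camera, times = fit_times)
  frames <- rf$frames + sample$T0
  set.seed(as.integer(seed))
  frames <- add_camera_noise(frames, noise, camera, sample)
  d <- dim(frames)
  xs <- rf$origin[1] + (seq_len(d[2]) - 0.5) * camera$pixel_size
  ys <- rf$origin[2] + (seq_len(d[1]) - 0.5) * camera$pixel_size
  cc <- which.min(abs(xs - location[1])); rr <- which.min(abs(ys - location[2]))
  half <- floor(fit_roi / 2)
  cols <- max(1, cc - half):min(d[2], cc + half)
  rows <- max(1, rr - half):min(d[1], rr + half)
  fits <- list()
  for (m in models) {
    rows_out <- lapply(seq_len(n_pulses), function(k) {
      z <- frames[rows, cols, k]
      loc <- if (m == "two_step") fit_peak_two_step(z, xs[cols], ys[rows], zeta0_sq)
             else fit_peak_single(z, xs[cols], ys[rows], m, zeta0_sq)
      if (!loc$converged) return(NULL)
      data.frame(pulse = k, x_c = loc$x_c, y_c = loc$y_c,
                 dTmax = loc$dTmax, zeta2 = loc$zeta2)
    })
    fits[[m]] <- do.call(rbind, rows_out)
  }
  summary <- do.call(rbind, lapply(names(fits), function(m) {
    f <- fits[[m]]
    if (is.null(f) || nrow(f) < 2) {
      return(data.frame(model = m, sigma_x = NA_real_, sigma_y = NA_real_,
                        dTmax = NA_real_, zeta2 = NA_real_, n_fits = 0L))
    }
    data.frame(model = m, sigma_x = sd(f$x_c), sigma_y = sd(f$y_c),
               dTmax = mean(f$dTmax), zeta2 = mean(f$zeta2), n_fits = nrow(f))
  }))
  list(dT_mean = mean(summary$dTmax, na.rm = TRUE), summary = summary, fits = fits)
}

#' Export localizations as CSV
#'
#' @param locs data frame from [localize_events()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path) {
  write.csv(locs, path, row.names = FALSE)
  invisible(path)
}
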