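#' Bin localizations onto the scan grid
#'
#' Renders the super-resolution image: every fitted peak center is
#' assigned to the scan pixel containing it (half-open bins
#' `[lo, hi)`, zero-based, anchored at the protocol origin); each pixel
#' takes the *largest* of its contributing amplitudes, and pixels whose
#' value falls below `dT_min` are set to zero. Localizations falling
#' outside the scan grid are dropped and counted.
#'
#' @param locs data frame of localizations (columns `x_c`, `y_c`,
#'   `dTmax`), lab-frame micrometres.
#' @param protocol the [scan_protocol] that defines the grid geometry.
#' @param dT_min rendering threshold, degC (0.3 suppresses spurious
#'   detections; 0.1 equals the camera sensitivity).
#' @return An object of class `superres_image`: list with `values`
#'   (`n_y` x `n_x` matrix of degC increments, 0 = empty), `counts`
#'   (contributing localizations per pixel), `pixel_size`, `origin`,
#'   `dT_min` and `n_outside`.
#' @export
bin_localizations <- function(locs, protocol, dT_min = 0.3) {
  .assert(inherits(protocol, "scan_protocol"), "`protocol` must be a scan_protocol")
  p <- protocol
  vals <- matrix(0, nrow = p$n_y, ncol = p$n_x)
  counts <- matrix(0L, nrow = p$n_y, ncol = p$n_x)
  sigma <- matrix(NA_real_, nrow = p$n_y, ncol = p$n_x)
  n_outside <- 0L
  if (nrow(locs)) {
    ix <- floor((locs$x_c - p$origin[1]) / p$pixel_size)   # 0-based bins
    iy <- floor((locs$y_c - p$origin[2]) / p$pixel_size)
    inside <- ix >= 0 & ix < p$n_x & iy >= 0 & iy < p$n_y
    n_outside <- sum(!inside)
    if (any(inside)) {
      ix <- ix[inside]; iy <- iy[inside]; dT <- locs$dTmax[inside]
      sig <- if ("sigma_x" %in% names(locs)) locs$sigma_x[inside] else
        rep(NA_real_, sum(inside))
      for (k in seq_along(ix)) {
        r <- iy[k] + 1L; c <- ix[k] + 1L
        if (dT[k] > vals[r, c]) {
          vals[r, c] <- dT[k]
          sigma[r, c] <- sig[k]
        }
        counts[r, c] <- counts[r, c] + 1L
      }
    }
  }
  sigma[vals < dT_min] <- NA_real_
  vals[vals < dT_min] <- 0
  structure(list(values = vals, counts = counts, sigma = sigma,
                 pixel_size = p$pixel_size,
                 origin = p$origin, dT_min = dT_min, n_outside = n_outside),
            class = "superres_image")
}

#' @export
print.superres_image <- function(x, ...) {
  cat(sprintf("superres_image: %d x %d px at %.3g um, dT_min %.2g degC, %d filled px (%d locs outside grid)\n",
              nrow(x$values), ncol(x$values), x$pixel_size, x$dT_min,
              sum(x$values > 0), x$n_outside))
  invisible(x)
}

#' @export
plot.superres_image <- function(x, ...) {
  nx <- ncol(x$values); ny <- nrow(x$values)
  graphics::image(x = x$origin[1] + (0:nx) * x$pixel_size,
                  y = x$origin[2] + (0:ny) * x$pixel_size,
                  z = t(x$values)[, ny:1, drop = FALSE],
                  col = grDevices::hcl.colors(64, "inferno"),
                  xlab = "x (um)", ylab = "y (um)", useRaster = TRUE, ...)
  invisible(x)
}

#' Temporal maximum projection
#'
#' Per-pixel maximum over all frames: the conventional, diffraction- and
#' diffusion-limited thermal image of the scanned area, used as the
#' low-resolution reference for the super-resolved reconstruction.
#'
#' @param stack a [thermal_stack()].
#' @return A `thermal_image`: the projected matrix with `pixel_size` and
#'   `origin` attributes.
#' @export
max_projection <- function(stack) {
  .assert(inherits(stack, "thermal_stack"), "`stack` must be a thermal_stack")
  mp <- apply(stack$frames, c(1, 2), max)
  structure(mp, pixel_size = stack$pixel_size, origin = stack$origin,
            class = c("thermal_image", "matrix"))
}

#' @export
print.thermal_image <- function(x, ...) {
  cat(sprintf("thermal_image: %d x %d px at %.3g um, range [%.3g, %.3g] degC\n",
              nrow(x), ncol(x), attr(x, "pixel_size"), min(x), max(x)))
  invisible(x)
}

#' Co-localization of a reconstruction with the ground truth
#'
#' Fraction of nonzero super-resolution pixels whose center lies within
#' `radius` of any absorbing cell of the ground-truth map.
#'
#' @param sr a `superres_image`.
#' @param truth the ground-truth [absorber_map] in the same lab frame.
#' @param radius co-localization radius, micrometres: either a scalar
#'   (typically twice the mean predicted localization uncertainty) or a
#'   matrix of per-pixel radii with the image's dimensions (typically
#'   twice the per-pixel uncertainty `sr$sigma`, mirroring the practice
#'   of extrapolating each point's error bar from the
#'   uncertainty-versus-amplitude curve).
#' @return Co-localization fraction in \[0, 1\]; `NA` (with a warning)
#'   for an empty reconstruction.
#' @export
overlay_report <- function(sr, truth, radius) {
  .assert(inherits(sr, "superres_image"), "`sr` must be a superres_image")
  .assert(inherits(truth, "absorber_map"), "`truth` must be an absorber_map")
  filled <- which(sr$values > 0, arr.ind = TRUE)
  if (nrow(filled) == 0) {
    warning("empty super-resolution image; co-localization undefined")
    return(NA_real_)
  }
  r_px <- if (is.matrix(radius)) {
    .assert(all(dim(radius) == dim(sr$values)), "per-pixel radius dims mismatch")
    radius[filled]
  } else {
    rep(radius, nrow(filled))
  }
  .assert(all(is.finite(r_px) & r_px >= 0), "radii must be finite and >= 0")
  px <- sr$origin[1] + (filled[, 2] - 0.5) * sr$pixel_size
  py <- sr$origin[2] + (filled[, 1] - 0.5) * sr$pixel_size
  abs_cells <- which(truth$values > 0, arr.ind = TRUE)
  if (nrow(abs_cells) == 0) return(0)
  ax <- truth$origin[1] + (abs_cells[, 2] - 0.5) * truth$pitch
  ay <- truth$origin[2] + (abs_cells[, 1] - 0.5) * truth$pitch
  hit <- vapply(seq_along(px), function(k) {
    any((ax - px[k])^2 + (ay - py[k])^2 <= r_px[k]^2)
  }, logical(1))
  mean(hit)
}

#' Write / read a super-resolution image as TIFF + JSON sidecar
#'
#' Values are stored in a 32-bit TIFF, linearly scaled to \[0, 1\]; the
#' scale, grid geometry and threshold go to the JSON sidecar
#' `<path>.json`.
#'
#' @param sr a `superres_image`.
#' @param path TIFF file path.
#' @return `write_superres` returns `path` invisibly; `read_superres`
#'   returns a `superres_image` (without provenance counts).
#' @export
write_superres <- function(sr, path) {
  vmax <- max(sr$values, 1e-12)
  tiff::writeTIFF(sr$values / vmax, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(list(pixel_size = sr$pixel_size, origin = sr$origin,
                            dT_min = sr$dT_min, value_max = vmax,
                            n_outside = sr$n_outside),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_superres
#' @export
read_superres <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- tiff::readTIFF(path) * side$value_max
  structure(list(values = vals, counts = NULL, pixel_size = side$pixel_size,
                 origin = unlist(side$origin), dT_min = side$dT_min,
                 n_outside = side$n_outside),
            class = "superres_image")
}
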