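# Common geometry accessor for profile extraction: values + pixel size +
# origin for superres_image, thermal_image, or a bare matrix (unit pixels).
image_geometry <- function(image) {
  if (inherits(image, "superres_image")) {
    list(values = image$values, pixel_size = image$pixel_size, origin = image$origin)
  } else if (inherits(image, "thermal_image")) {
    list(values = unclass(image), pixel_size = attr(image, "pixel_size"),
         origin = attr(image, "origin"))
  } else if (is.matrix(image)) {
    list(values = image, pixel_size = 1, origin = c(0, 0))
  } else {
    stop("unsupported image type", call. = FALSE)
  }
}

bilinear_sample <- function(g, x, y) {
  # fractional cell coordinates (cell centers at origin + (i - 0.5) * pitch)
  fx <- (x - g$origin[1]) / g$pixel_size + 0.5
  fy <- (y - g$origin[2]) / g$pixel_size + 0.5
  nx <- ncol(g$values); ny <- nrow(g$values)
  x0 <- pmin(pmax(floor(fx), 1), nx - 1); y0 <- pmin(pmax(floor(fy), 1), ny - 1)
  wx <- pmin(pmax(fx - x0, 0), 1); wy <- pmin(pmax(fy - y0, 0), 1)
  v00 <- g$values[cbind(y0, x0)]; v01 <- g$values[cbind(y0, x0 + 1)]
  v10 <- g$values[cbind(y0 + 1, x0)]; v11 <- g$values[cbind(y0 + 1, x0 + 1)]
  (1 - wy) * ((1 - wx) * v00 + wx * v01) + wy * ((1 - wx) * v10 + wx * v11)
}

#' Extract an intensity profile along a line
#'
#' Samples the image by bilinear interpolation at image-pixel spacing
#' along the segment from `start` to `end`, averaging over `width`
#' micrometres perpendicular to the line (also sampled at pixel
#' spacing).
#'
#' @param image a `superres_image`, `thermal_image`, or plain matrix.
#' @param start,end length-2 numeric, segment endpoints, micrometres.
#' @param width perpendicular averaging width, micrometres (0 = single
#'   line).
#' @param spacing sample spacing, micrometres (default: the image pixel
#'   size).
#' @return A data frame of class `profile` with columns `pos`
#'   (micrometres along the line, starting at 0) and `value`.
#' @export
extract_profile <- function(image, start, end, width = 0, spacing = NULL) {
  g <- image_geometry(image)
  start <- as.numeric(start); end <- as.numeric(end)
  len <- sqrt(sum((end - start)^2))
  .assert(len > 0, "zero-length profile line")
  spacing <- spacing %||% g$pixel_size
  u <- (end - start) / len                      # along-line unit vector
  v <- c(-u[2], u[1])                           # perpendicular unit vector
  pos <- seq(0, len, by = spacing)
  offs <- if (width > 0) seq(-width / 2, width / 2, by = spacing) else 0
  vals <- vapply(pos, function(p) {
    ctr <- start + p * u
    mean(bilinear_sample(g, ctr[1] + offs * v[1], ctr[2] + offs * v[2]))
  }, numeric(1))
  structure(data.frame(pos = pos, value = vals),
            spacing = spacing, class = c("profile", "data.frame"))
}

# Local maxima of a vector with plateau handling: a run of equal values
# strictly above both flanks counts as one maximum at its center.
local_maxima <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  out <- integer(0)
  for (i in seq_len(k)) {
    left_ok <- i == 1 || r$values[i - 1] < r$values[i]
    right_ok <- i == k || r$values[i + 1] < r$values[i]
    if (i > 1 && i < k && left_ok && right_ok) {
      out <- c(out, as.integer(round((starts[i] + ends[i]) / 2)))
    }
  }
  out
}

#' Contrast between adjacent profile peaks
#'
#' After light smoothing (3-sample moving mean, optional), finds the
#' local maxima of the profile and, for each adjacent pair, the dip
#' between them; the contrast is
#' `100 * (mean(peak1, peak2) - dip) / mean(peak1, peak2)` -- the
#' definition under which two Airy patterns at the Rayleigh separation
#' give the canonical ~26.4% (see [rayleigh_contrast_threshold()]).
#'
#' @param profile a `profile` from [extract_profile()] (or any data
#'   frame with `pos`, `value`).
#' @param smooth apply the 3-sample moving mean before peak finding.
#' @param min_separation optional minimum peak separation (same units as
#'   `pos`): maxima closer than this are merged keeping the larger, so
#'   that small ripples on top of a broad peak are not counted as
#'   separate structure.
#' @return Data frame with one row per adjacent peak pair: `pos_a`,
#'   `pos_b`, `peak_a`, `peak_b`, `dip`, `contrast` (percent); zero rows
#'   when fewer than two maxima are found.
#' @export
adjacent_peak_contrast <- function(profile, smooth = TRUE, min_separation = NULL) {
  v <- profile$value
  if (smooth && length(v) >= 3) {
    v <- as.numeric(stats::filter(v, rep(1 / 3, 3), sides = 2))
    v[1] <- profile$value[1]; v[length(v)] <- profile$value[length(v)]
  }
  idx <- local_maxima(v)
  if (!is.null(min_separation) && length(idx) > 1) {
    keep <- integer(0)
    for (i in idx[order(-v[idx])]) {
      if (all(abs(profile$pos[i] - profile$pos[keep]) >= min_separation)) keep <- c(keep, i)
    }
    idx <- sort(keep)
  }
  empty <- data.frame(pos_a = numeric(0), pos_b = numeric(0), peak_a = numeric(0),
                      peak_b = numeric(0), dip = numeric(0), contrast = numeric(0))
  if (length(idx) < 2) return(empty)
  out <- lapply(seq_len(length(idx) - 1), function(k) {
    a <- idx[k]; b <- idx[k + 1]
    dip <- min(v[a:b])
    pk <- mean(c(v[a], v[b]))
    data.frame(pos_a = profile$pos[a], pos_b = profile$pos[b],
               peak_a = v[a], peak_b = v[b], dip = dip,
               contrast = 100 * (pk - dip) / pk)
  })
  do.call(rbind, out)
}

#' Rayleigh dip contrast from first principles
#'
#' Numerically computes the dip contrast of the sum of two equal,
#' incoherent Airy intensity patterns `I(v) = (2 J1(v) / v)^2` separated
#' by the first-zero distance `v0 = 3.8317` (the Rayleigh criterion):
#' two points at this separation are "just resolved", with a saddle
#' about 26.4% below the peaks.
#'
#' @param separation center separation in reduced units (default: the
#'   Airy first zero).
#' @param step sampling step in reduced units; the result is converged
#'   for `step <= v0 / 200`.
#' @return Dip contrast, percent (0 when the two peaks have merged).
#' @export
rayleigh_contrast_threshold <- function(separation = 3.8317, step = 3.8317 / 400) {
  airy <- function(v) ifelse(abs(v) < 1e-9, 1, (2 * besselJ(abs(v), 1) / v)^2)
  v <- seq(-separation, 2 * separation, by = step)
  total <- airy(v) + airy(v - separation)
  prof <- data.frame(pos = v, value = total)
  ct <- adjacent_peak_contrast(prof, smooth = FALSE,
                               min_separation = separation / 2)
  if (nrow(ct) == 0) return(0)
  max(ct$contrast)
}

#' Resolution gain
#'
#' Fold improvement of an achieved resolution over a reference
#' (`reference / achieved`), e.g. the diffraction-limited prediction or
#' the camera's effective resolution in conventional operation.
#'
#' @param reference,achieved resolutions in the same units (> 0).
#' @return Dimensionless gain.
#' @export
resolution_gain <- function(reference, achieved) {
  .assert(all(reference > 0) && all(achieved > 0), "resolutions must be > 0")
  reference / achieved
}

#' Abbe diffraction limit
#'
#' `lambda / (2 NA)`: the two-point resolution bound set by diffraction
#' at the collecting optics. For far-infrared thermal wavelengths at the
#' low numerical aperture of thermal-camera lenses this is hundreds of
#' micrometres.
#'
#' @param wavelength wavelength, micrometres.
#' @param na numerical aperture, in (0, 1\].
#' @return Resolution limit, micrometres.
#' @export
abbe_limit <- function(wavelength, na) {
  .assert(all(na > 0 & na <= 1), "`na` must be in (0, 1]")
  wavelength / (2 * na)
}

#' Export a profile or contrast table as CSV
#'
#' @param x a `profile` or contrast data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
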