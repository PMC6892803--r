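#' Absorber maps
#'
#' An `absorber_map` is a high-resolution grid of absorptance values in
#' \[0, 1\] standing in for the distribution of light-absorbing,
#' heat-releasing entities (printed ink, nanoparticle clusters). It is the
#' ground truth that super-resolution reconstructions are compared against.
#'
#' @param values numeric matrix of absorptance values in \[0, 1\],
#'   indexed `[row, col]` = `[y, x]`.
#' @param pitch grid cell size, micrometres.
#' @param origin length-2 numeric, lab-frame position (micrometres) such
#'   that the center of cell `(1, 1)` sits at `origin + pitch / 2`.
#' @param centers optional data frame with columns `x`, `y` (micrometres)
#'   recording ground-truth feature positions.
#' @return An object of class `absorber_map`.
#' @export
absorber_map <- function(values, pitch, origin = c(0, 0), centers = NULL) {
  .assert(is.matrix(values) && length(values) > 0, "`values` must be a non-empty matrix")
  .assert(all(is.finite(values)) && all(values >= 0) && all(values <= 1),
          "absorptance values must lie in [0, 1]")
  .assert(is.numeric(pitch) && length(pitch) == 1 && pitch > 0, "`pitch` must be > 0")
  .assert(length(origin) == 2, "`origin` must have length 2")
  if (!is.null(centers)) {
    .assert(is.data.frame(centers) && all(c("x", "y") %in% names(centers)),
            "`centers` must be a data frame with columns x, y")
  }
  structure(list(values = values, pitch = pitch, origin = as.numeric(origin),
                 centers = centers),
            class = "absorber_map")
}

#' @export
print.absorber_map <- function(x, ...) {
  cat(sprintf("absorber_map: %d x %d cells, pitch %.3g um, field %.3g x %.3g um\n",
              nrow(x$values), ncol(x$values), x$pitch,
              ncol(x$values) * x$pitch, nrow(x$values) * x$pitch))
  cat(sprintf("  absorbing fraction: %.3f; ground-truth features: %d\n",
              mean(x$values > 0), if (is.null(x$centers)) 0L else nrow(x$centers)))
  invisible(x)
}

# cell-center coordinates of a map (x along columns, y along rows)
map_axes <- function(map) {
  list(x = map$origin[1] + (seq_len(ncol(map$values)) - 0.5) * map$pitch,
       y = map$origin[2] + (seq_len(nrow(map$values)) - 0.5) * map$pitch)
}

#' Stripe-grid absorber pattern
#'
#' Vertical stripes of absorptance 1 on a zero background, mimicking a
#' printed grid of uniform ink stripes of given width and spacing. Stripe
#' centers are recorded as ground-truth metadata.
#'
#' @param stripe_width stripe width, micrometres.
#' @param gap spacing between stripe edges, micrometres.
#' @param n_stripes number of stripes.
#' @param pitch grid cell size, micrometres; must be at most
#'   `stripe_width / 4` so each stripe is well sampled.
#' @param margin background margin on each side, micrometres.
#' @param height field height, micrometres (default: the field width).
#' @return An [absorber_map].
#' @export
make_stripe_grid <- function(stripe_width, gap, n_stripes, pitch,
                             margin = (stripe_width + gap) / 2, height = NULL) {
  .assert(stripe_width > 0 && gap > 0 && pitch > 0 && n_stripes >= 1,
          "stripe_width, gap, pitch must be > 0 and n_stripes >= 1")
  .assert(pitch <= stripe_width / 4,
          "`pitch` must be <= stripe_width / 4 to sample each stripe")
  width <- n_stripes * stripe_width + (n_stripes - 1) * gap + 2 * margin
  height <- height %||% width
  nx <- max(1L, round(width / pitch))
  ny <- max(1L, round(height / pitch))
  xc <- (seq_len(nx) - 0.5) * pitch
  starts <- margin + (seq_len(n_stripes) - 1) * (stripe_width + gap)
  vals <- matrix(0, nrow = ny, ncol = nx)
  for (s in starts) {
    vals[, xc >= s & xc < s + stripe_width] <- 1
  }
  centers <- data.frame(x = starts + stripe_width / 2, y = ny * pitch / 2)
  absorber_map(vals, pitch, centers = centers)
}

#' Sparse disk-cluster absorber pattern
#'
#' Disks of absorptance 1 at uniformly drawn centers, emulating isolated
#' nanoparticle clusters scattered across a field. Overlap is allowed. The
#' drawn centers are retained as ground truth.
#'
#' @param n_clusters number of clusters (0 gives an empty map).
#' @param cluster_radius disk radius, micrometres (at least `pitch` so that
#'   every stored center lies on an absorbing cell).
#' @param field length-2 numeric, field size `(width, height)` micrometres.
#' @param seed integer seed fixing the cluster positions.
#' @param pitch grid cell size, micrometres.
#' @return An [absorber_map].
#' @export
make_sparse_clusters <- function(n_clusters, cluster_radius, field, seed, pitch) {
  .assert(length(field) == 2 && all(field > 0), "`field` must be (width, height) > 0")
  .assert(pitch > 0, "`pitch` must be > 0")
  .assert(n_clusters >= 0, "`n_clusters` must be >= 0")
  .assert(cluster_radius >= pitch, "`cluster_radius` must be >= `pitch`")
  .assert(all(field >= 2 * cluster_radius), "field too small for the requested clusters")
  nx <- max(1L, round(field[1] / pitch))
  ny <- max(1L, round(field[2] / pitch))
  vals <- matrix(0, nrow = ny, ncol = nx)
  if (n_clusters == 0) {
    return(absorber_map(vals, pitch, centers = data.frame(x = numeric(0), y = numeric(0))))
  }
  set.seed(as.integer(seed))
  cx <- runif(n_clusters, cluster_radius, field[1] - cluster_radius)
  cy <- runif(n_clusters, cluster_radius, field[2] - cluster_radius)
  xc <- (seq_len(nx) - 0.5) * pitch
  yc <- (seq_len(ny) - 0.5) * pitch
  for (k in seq_len(n_clusters)) {
    dx2 <- outer((yc - cy[k])^2, (xc - cx[k])^2, `+`)
    vals[dx2 <= cluster_radius^2] <- 1
  }
  absorber_map(vals, pitch, centers = data.frame(x = cx, y = cy))
}

#' Uniform absorbing square
#'
#' A filled square of absorptance 1 centered in a larger zero field; the
#' standard target for localization-repeatability runs on a spatially
#' uniform absorber.
#'
#' @param side square side, micrometres; must be at least `pitch`.
#' @param pitch grid cell size, micrometres.
#' @param field field side, micrometres (default `2 * side`).
#' @return An [absorber_map].
#' @export
make_uniform_square <- function(side, pitch, field = 2 * side) {
  .assert(pitch > 0, "`pitch` must be > 0")
  .assert(side >= pitch, "`side` must be at least one grid cell (side >= pitch)")
  .assert(field >= side, "`field` must be >= `side`")
  n <- max(1L, round(field / pitch))
  cc <- (seq_len(n) - 0.5) * pitch
  lo <- (field - side) / 2
  inside <- cc >= lo & cc < lo + side
  vals <- matrix(0, n, n)
  vals[inside, inside] <- 1
  absorber_map(vals, pitch, centers = data.frame(x = field / 2, y = field / 2))
}

#' Sample thermal model
#'
#' Lumped thermal description of the specimen: emissivity for gray-body
#' radiometry, in-plane thermal diffusivity, baseline temperature, a
#' heating amplitude `A` (temperature rise rate at the beam peak for unit
#' absorptance, lumping absorbed power, heat capacity and section
#' thickness), and a Newton-cooling loss time `tau_d` to the environment.
#'
#' @param emissivity dimensionless, in (0, 1\].
#' @param diffusivity in-plane thermal diffusivity, um^2/s.
#' @param T0 baseline temperature, degrees Celsius.
#' @param A heating amplitude at unit absorptance, degrees Celsius per second.
#' @param tau_d heat-loss time constant, seconds.
#' @return An object of class `sample_model`.
#' @export
sample_model <- function(emissivity, diffusivity, T0 = 19.85, A = 1, tau_d = 1) {
  .assert(emissivity > 0 && emissivity <= 1, "`emissivity` must be in (0, 1]")
  .assert(diffusivity >= 0, "`diffusivity` must be >= 0")
  .assert(A >= 0, "`A` must be >= 0")
  .assert(tau_d > 0, "`tau_d` must be > 0")
  .assert(T0 > -273.15, "`T0` below absolute zero")
  structure(list(emissivity = emissivity, diffusivity = diffusivity,
                 T0 = T0, A = A, tau_d = tau_d),
            class = "sample_model")
}

#' Sample presets
#'
#' `sample_ink()` describes a printed-ink test pattern on film
#' (emissivity 0.8); `sample_biopsy()` a thin tissue section with
#' exogenous photothermal nanoparticles (emissivity 0.95). Diffusivities
#' are typical of polymer film and water-rich tissue; the loss time
#' `tau_d = 0.15` s reflects the fast Newton cooling of a ~10 um section
#' into its substrate; the heating amplitudes are set so that the
#' default beam and pulse lengths produce camera-fitted temperature
#' increments in the 0.3--5 degC range.
#'
#' @param ... overrides passed on to [sample_model()].
#' @return A `sample_model`.
#' @export
sample_ink <- function(...) {
  args <- list(emissivity = 0.8, diffusivity = 1.0e5, T0 = 19.85,
               A = 2500, tau_d = 0.15)
  do.call(sample_model, utils::modifyList(args, list(...)))
}

#' @rdname sample_ink
#' @export
sample_biopsy <- function(...) {
  args <- list(emissivity = 0.95, diffusivity = 1.3e5, T0 = 19.85,
               A = 3000, tau_d = 0.15)
  do.call(sample_model, utils::modifyList(args, list(...)))
}

#' Excitation beam model
#'
#' Gaussian excitation beam. `diameter_1e2` is the 1/e^2 intensity
#' diameter `2 * w0`; the beam intensity profile is
#' `exp(-2 r^2 / w0^2)`, i.e. it has spatial variance `w0^2 / 4` per axis.
#'
#' @param wavelength excitation wavelength, nanometres.
#' @param power laser power on the sample plane, milliwatts (metadata; the
#'   thermal effect of power is lumped into [sample_model()]'s `A`).
#' @param diameter_1e2 1/e^2 intensity diameter, micrometres.
#' @return An object of class `beam_model`.
#' @export
beam_model <- function(wavelength = 633, power = 15, diameter_1e2 = 22) {
  .assert(diameter_1e2 > 0, "`diameter_1e2` must be > 0")
  .assert(power >= 0, "`power` must be >= 0")
  structure(list(wavelength = wavelength, power = power,
                 diameter_1e2 = diameter_1e2, w0 = diameter_1e2 / 2),
            class = "beam_model")
}

#' Write / read an absorber map as TIFF + JSON sidecar
#'
#' The absorptance grid is stored as a single-page 32-bit TIFF; pitch,
#' origin and ground-truth centers go to a JSON sidecar at
#' `<path>.json`.
#'
#' @param map an [absorber_map].
#' @param path TIFF file path.
#' @return `write_absorber_map` returns `path` invisibly;
#'   `read_absorber_map` returns an [absorber_map].
#' @export
write_absorber_map <- function(map, path) {
  .assert(inherits(map, "absorber_map"), "`map` must be an absorber_map")
  tiff::writeTIFF(map$values, path, bits.per.sample = 32L, compression = "none")
  side <- list(pitch = map$pitch, origin = map$origin)
  if (!is.null(map$centers)) side$centers <- map$centers
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_absorber_map
#' @export
read_absorber_map <- function(path) {
  vals <- tiff::readTIFF(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  centers <- side$centers
  if (!is.null(centers)) centers <- as.data.frame(centers)
  absorber_map(vals, pitch = side$pitch, origin = unlist(side$origin),
               centers = centers)
}
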