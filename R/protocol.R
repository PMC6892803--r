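#' Modulated raster-scan protocol
#'
#' Describes the scan grid and the sparse activation lattice. The sample
#' is raster scanned `dx * dy` times; during scan `s` only pixels whose
#' grid indices are congruent to the s-th lattice offset modulo
#' `(dx, dy)` are laser activated, so that simultaneously hot spots stay
#' at least `dx * pixel_size` (horizontal) and `dy * pixel_size`
#' (vertical) apart. The laser dwells `tau_on` seconds on activated
#' pixels (shutter open) and `tau_off` on silent ones (shutter closed).
#'
#' @param n_x,n_y scan-grid size in pixels.
#' @param pixel_size scan pixel size, micrometres (square pixels).
#' @param lattice integer length-2, lattice spacings `(dx, dy)` in scan
#'   pixels.
#' @param tau_on activation dwell time, seconds.
#' @param tau_off silent dwell time, seconds (shutter closed).
#' @param origin lab-frame position of the corner of scan pixel (1, 1),
#'   micrometres.
#' @return An object of class `scan_protocol`.
#' @export
scan_protocol <- function(n_x, n_y, pixel_size, lattice, tau_on,
                          tau_off = 0.002, origin = c(0, 0)) {
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  lattice <- as.integer(lattice)
  .assert(length(lattice) == 2, "`lattice` must be (dx, dy)")
  .assert(n_x >= 1 && n_y >= 1, "grid must be non-empty")
  .assert(lattice[1] >= 1 && lattice[1] <= n_x &&
          lattice[2] >= 1 && lattice[2] <= n_y,
          "lattice spacings must satisfy 1 <= dx <= n_x, 1 <= dy <= n_y")
  .assert(pixel_size > 0, "`pixel_size` must be > 0")
  .assert(tau_on > 0 && tau_off > 0, "dwell times must be > 0")
  structure(list(n_x = n_x, n_y = n_y, pixel_size = pixel_size,
                 lattice = lattice, tau_on = tau_on, tau_off = tau_off,
                 origin = as.numeric(origin)),
            class = "scan_protocol")
}

#' @export
print.scan_protocol <- function(x, ...) {
  cat(sprintf("scan_protocol: %d x %d px at %.3g um, lattice (%d, %d), tau_on %.3g s, tau_off %.3g s\n",
              x$n_x, x$n_y, x$pixel_size, x$lattice[1], x$lattice[2],
              x$tau_on, x$tau_off))
  cat(sprintf("  %d scans, %g events/scan (if commensurate), t_tot %.4g s\n",
              prod(x$lattice), x$n_x * x$n_y / prod(x$lattice), total_time(x)))
  invisible(x)
}

#' Build the ordered illumination schedule
#'
#' Expands a [scan_protocol] into the ordered sequence of laser pulses.
#' Scan `s` (1-based) uses lattice offset `(p, q)` with
#' `p = (s - 1) %% dx`, `q = (s - 1) %/% dx` (row-major offset order);
#' within a scan, activated pixels are visited in raster order (rows top
#' to bottom, columns left to right). Time advances by `tau_on` at
#' activated pixels and `tau_off` at silent ones, so every grid pixel is
#' traversed in every scan but only the lattice subset is illuminated.
#' Over the full schedule every scan pixel is activated exactly once.
#'
#' @param protocol a [scan_protocol].
#' @return A data frame of class `illumination_schedule` with columns
#'   `event`, `scan`, `i`, `j` (0-based scan indices), `x0`, `y0`
#'   (pulse center, micrometres), `t0` (start time, seconds) and
#'   `duration` (`= tau_on`). The protocol is attached as an attribute.
#' @export
build_schedule <- function(protocol) {
  .assert(inherits(protocol, "scan_protocol"), "`protocol` must be a scan_protocol")
  p <- protocol
  dx <- p$lattice[1]; dy <- p$lattice[2]
  n_scans <- dx * dy
  out <- vector("list", n_scans)
  scan_start <- 0
  for (s in seq_len(n_scans)) {
    px <- (s - 1) %% dx
    qy <- (s - 1) %/% dx
    ii <- seq(px, p$n_x - 1, by = dx)
    jj <- seq(qy, p$n_y - 1, by = dy)
    grid <- expand.grid(i = ii, j = jj)      # raster order: j outer, i inner
    grid <- grid[order(grid$j, grid$i), , drop = FALSE]
    m <- grid$j * p$n_x + grid$i             # 0-based raster position
    n_act_before <- seq_along(m) - 1
    t0 <- scan_start + n_act_before * p$tau_on + (m - n_act_before) * p$tau_off
    out[[s]] <- data.frame(scan = s, i = grid$i, j = grid$j,
                           x0 = p$origin[1] + (grid$i + 0.5) * p$pixel_size,
                           y0 = p$origin[2] + (grid$j + 0.5) * p$pixel_size,
                           t0 = t0, duration = p$tau_on)
    n_act <- length(m)
    scan_start <- scan_start + n_act * p$tau_on +
      (p$n_x * p$n_y - n_act) * p$tau_off
  }
  sched <- do.call(rbind, out)
  sched <- cbind(event = seq_len(nrow(sched)), sched)
  rownames(sched) <- NULL
  attr(sched, "protocol") <- p
  class(sched) <- c("illumination_schedule", "data.frame")
  sched
}

#' Total acquisition time of a protocol
#'
#' Closed-form duration of the full modulated scan:
#' `t_tot = n_x n_y tau_on + n_x n_y tau_off (dx dy - 1)`.
#' Every pixel is activated once (contributing `tau_on`) and traversed
#' silently in the remaining `dx dy - 1` scans (contributing `tau_off`
#' each). Equals the traversal end time of the schedule built by
#' [build_schedule()].
#'
#' @param protocol a [scan_protocol].
#' @return Total time, seconds.
#' @export
total_time <- function(protocol) {
  .assert(inherits(protocol, "scan_protocol"), "`protocol` must be a scan_protocol")
  n <- protocol$n_x * protocol$n_y
  n * protocol$tau_on + n * protocol$tau_off * (prod(protocol$lattice) - 1)
}

#' Minimum spacing between concurrent activations
#'
#' Diffusion-length heuristic for how far apart (in space, or else in
#' time) two illumination events must be for their temperature peaks to
#' remain separable: a temperature spot born with spatial variance
#' `w0^2/4` grows diffusively, so after `tau_on` its footprint is
#' `sqrt(w0^2/4 + 4 D tau_on)`; the safety factor `safety_k` (default 3)
#' scales both that length and the slower of pulse length and heat-loss
#' time.
#'
#' @param sample a [sample_model].
#' @param tau_on activation time, seconds.
#' @param beam a [beam_model].
#' @param safety_k dimensionless safety factor.
#' @return List with `dx_min` (micrometres) and `dt_min` (seconds).
#' @export
min_separation <- function(sample, tau_on, beam, safety_k = 3) {
  .assert(inherits(sample, "sample_model"), "`sample` must be a sample_model")
  .assert(inherits(beam, "beam_model"), "`beam` must be a beam_model")
  .assert(tau_on > 0, "`tau_on` must be > 0")
  list(dx_min = safety_k * sqrt(beam$w0^2 / 4 + 4 * sample$diffusivity * tau_on),
       dt_min = safety_k * max(tau_on, sample$tau_d))
}

#' Flag schedule pairs that violate the separation rule
#'
#' Reports every pair of illumination events closer than `dx_min` in
#' space and simultaneously closer than `dt_min` in time. Violations are
#' reported, not fatal: overlapping peaks degrade localization but do not
#' invalidate the rest of the schedule.
#'
#' @param schedule an `illumination_schedule` (or any data frame with
#'   `x0`, `y0`, `t0` columns).
#' @param dx_min,dt_min separation thresholds from [min_separation()].
#' @return Data frame of violating pairs (`event_a`, `event_b`,
#'   `distance_um`, `dt_s`); zero rows when the schedule is clean.
#' @export
validate_schedule <- function(schedule, dx_min, dt_min) {
  s <- schedule[order(schedule$t0), , drop = FALSE]
  n <- nrow(s)
  res <- list()
  for (a in seq_len(max(0, n - 1))) {
    b <- a + 1
    while (b <= n && s$t0[b] - s$t0[a] < dt_min) {
      d <- sqrt((s$x0[a] - s$x0[b])^2 + (s$y0[a] - s$y0[b])^2)
      if (d < dx_min) {
        res[[length(res) + 1]] <- data.frame(
          event_a = s$event[a], event_b = s$event[b],
          distance_um = d, dt_s = s$t0[b] - s$t0[a])
      }
      b <- b + 1
    }
  }
  if (length(res) == 0) {
    data.frame(event_a = integer(0), event_b = integer(0),
               distance_um = numeric(0), dt_s = numeric(0))
  } else {
    do.call(rbind, res)
  }
}

#' Export a schedule as CSV
#'
#' @param schedule an `illumination_schedule`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  write.csv(as.data.frame(schedule)[, c("event", "i", "j", "x0", "y0", "t0", "duration")],
            path, row.names = FALSE)
  invisible(path)
}
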