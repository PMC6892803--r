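#' Default sliding-window length for trace peak detection
#'
#' `max(5, round(2 * tau_on * f_rate))` frames: long enough to bracket
#' the exponential-like rise and the early decay of one laser pulse.
#'
#' @param tau_on activation time, seconds.
#' @param f_rate camera frame rate, Hz.
#' @return Window length in frames.
#' @export
default_window <- function(tau_on, f_rate) max(5L, as.integer(round(2 * tau_on * f_rate)))

# 1D Gaussian on a linear baseline, fit to a short trace segment by
# Levenberg-Marquardt. The linear term absorbs the slowly decaying warm
# background left by earlier pulses, which would otherwise widen or
# displace the fitted peak.
fit_gauss1d <- function(y) {
  n <- length(y)
  t <- seq_len(n)
  tm <- (n + 1) / 2
  base0 <- median(y)
  amp0 <- max(y) - base0
  par0 <- c(amp = amp0, tc = which.max(y), s = n / 6, base = base0, slope = 0)
  resid_fun <- function(p) {
    y - (p[4] + p[5] * (t - tm) + p[1] * exp(-(t - p[2])^2 / (2 * p[3]^2)))
  }
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par0, fn = resid_fun,
                         lower = c(-Inf, 1, 0.5, -Inf, -Inf),
                         upper = c(Inf, n, n, Inf, Inf),
                         control = minpack.lm::nls.lm.control(maxiter = 60))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  list(amp = p[1], tc = p[2], s = p[3], base = p[4], slope = p[5],
       converged = fit$info %in% 1:4)
}

#' Detect temperature peaks in one pixel time trace
#'
#' Slides a fixed-length window one frame at a time over the trace and
#' fits a 1D symmetric Gaussian plus baseline at each position (the
#' Gaussian reasonably approximates the exponential-like rise and decay
#' for short pulses). A candidate is accepted when the fitted center
#' falls in the central third of the window, the fitted amplitude
#' reaches `amp_threshold`, and the fitted width lies between
#' `window / 8` and `window / 3` frames (an isolated-sample noise spike
#' is much narrower than any real temperature transient, which rises
#' over `tau_on`, while a "peak" as wide as the window is a baseline
#' drift in disguise -- its amplitude and the free baseline are
#' degenerate);
#' overlapping candidates closer than half a window are merged keeping
#' the larger amplitude, and merged peaks supported by a single window
#' position are discarded (a real transient is re-found at several
#' consecutive positions, a noise excursion is not). Window positions whose raw excursion (max minus
#' mean) is too small to yield an acceptable amplitude, or whose raw
#' maximum is not in the central third, are skipped without fitting.
#'
#' @param trace numeric vector, temperature versus time, degC.
#' @param f_rate frame rate, Hz; frame `k` is at time `(k - 1) / f_rate`.
#' @param window window length, frames (>= 5).
#' @param amp_threshold minimum fitted amplitude, degC.
#' @return Data frame with one row per detected peak: `frame` (1-based
#'   index of the local temperature maximum near the fitted center),
#'   `time` (`(frame - 1) / f_rate`, s), `amplitude` (degC) and
#'   `width_s` (fitted Gaussian sigma, s), sorted by time.
#' @export
detect_trace_peaks <- function(trace, f_rate, window, amp_threshold) {
  .assert(all(is.finite(trace)), "trace contains non-finite values")
  window <- as.integer(window)
  .assert(window >= 5, "`window` must be >= 5 frames")
  .assert(length(trace) >= window, "trace shorter than the window")
  n <- length(trace)
  seg <- stats::embed(trace, window)[, window:1, drop = FALSE]  # rows: positions
  npos <- nrow(seg)
  imax <- max.col(seg, ties.method = "first")
  vmax <- seg[cbind(seq_len(npos), imax)]
  excur <- vmax - rowMeans(seg)
  lo_third <- window / 3; hi_third <- 2 * window / 3
  candidates <- which(excur >= 0.5 * amp_threshold &
                      imax > lo_third & imax <= ceiling(hi_third))
  acc <- vector("list", length(candidates))
  for (k in seq_along(candidates)) {
    p <- candidates[k]
    f <- fit_gauss1d(seg[p, ])
    if (is.null(f) || !f$converged) next
    if (f$amp < amp_threshold) next
    if (f$tc <= lo_third || f$tc > hi_third) next
    if (f$s < window / 8 || f$s > window / 3) next
    acc[[k]] <- data.frame(pos = p + f$tc - 1, amplitude = f$amp, s = f$s)
  }
  acc <- do.call(rbind, acc)
  empty <- data.frame(time = numeric(0), frame = integer(0),
                      amplitude = numeric(0), width_s = numeric(0))
  if (is.null(acc) || nrow(acc) == 0) return(empty)
  # merge overlapping candidates, keeping the larger amplitude; a real
  # transient is re-found at several consecutive window positions, so
  # singleton candidates (seen at one position only) are discarded
  acc <- acc[order(-acc$amplitude), , drop = FALSE]
  keep <- logical(0); kept_pos <- numeric(0); support <- integer(0)
  for (k in seq_len(nrow(acc))) {
    d <- abs(acc$pos[k] - kept_pos)
    if (all(d >= window / 2)) {
      keep <- c(keep, k); kept_pos <- c(kept_pos, acc$pos[k])
      support <- c(support, 1L)
    } else {
      j <- which.min(d)
      support[j] <- support[j] + 1L
    }
  }
  acc <- acc[keep, , drop = FALSE]
  acc <- acc[support >= 2, , drop = FALSE]
  if (nrow(acc) == 0) return(empty)
  acc <- acc[order(acc$pos), , drop = FALSE]
  # store the temporal coordinate of the local temperature maximum: the
  # raw argmax near the fitted center (the symmetric Gaussian is only an
  # approximation to the asymmetric rise/decay, so its center is slightly
  # early; the raw maximum is not)
  frame <- vapply(acc$pos, function(p) {
    lo <- max(1L, as.integer(floor(p - window / 4)))
    hi <- min(n, as.integer(ceiling(p + window / 4)))
    lo + which.max(trace[lo:hi]) - 1L
  }, integer(1))
  data.frame(time = (frame - 1) / f_rate,
             frame = frame,
             amplitude = acc$amplitude,
             width_s = acc$s / f_rate)
}

#' Region of interest from the temporal maximum projection
#'
#' The scanned area lights up in the maximum projection over time; this
#' returns the bounding box of pixels whose temporal maximum exceeds the
#' baseline estimate (median of the per-pixel temporal minima) by
#' `3 * netd`, padded by 2 pixels and clipped to the frame. If no pixel
#' exceeds the threshold, the full frame is returned with a warning.
#'
#' @param stack a [thermal_stack()].
#' @param netd noise scale, degC (default: the stack's camera NETD).
#' @return List with `col` and `row` integer ranges (`c(lo, hi)`).
#' @export
roi_from_max_projection <- function(stack, netd = NULL) {
  .assert(inherits(stack, "thermal_stack"), "`stack` must be a thermal_stack")
  netd <- netd %||% (if (!is.null(stack$camera)) stack$camera$netd else 0.1)
  mp <- apply(stack$frames, c(1, 2), max)
  t0_est <- median(apply(stack$frames, c(1, 2), min))
  hot <- which(mp > t0_est + 3 * netd, arr.ind = TRUE)
  d <- dim(stack$frames)
  if (nrow(hot) == 0) {
    warning("no pixel above the ROI threshold; using the full frame")
    return(list(col = c(1L, d[2]), row = c(1L, d[1])))
  }
  list(col = c(max(1L, min(hot[, 2]) - 2L), min(d[2], max(hot[, 2]) + 2L)),
       row = c(max(1L, min(hot[, 1]) - 2L), min(d[1], max(hot[, 1]) + 2L)))
}

#' Detect illumination events across a stack
#'
#' Runs [detect_trace_peaks()] on every pixel trace inside the region of
#' interest, then groups detections that stem from the same laser pulse:
#' one pulse lights up several neighbouring camera pixels through heat
#' diffusion and optical blur, so detections whose peak frames differ by
#' at most one and whose pixels are 8-connected are merged (transitively)
#' into a single event, represented by the pixel with the largest fitted
#' amplitude.
#'
#' @param stack a [thermal_stack()].
#' @param roi list with `col`, `row` ranges as returned by
#'   [roi_from_max_projection()]; `NULL` computes it from the stack.
#' @param window sliding-window length, frames.
#' @param amp_threshold minimum fitted 1D amplitude, degC.
#' @return Data frame with one row per event: `col`, `row` (camera pixel
#'   indices), `frame`, `time`, `amplitude`, `width_s`, `n_pixels`
#'   (detections merged into the event), sorted by time.
#' @export
detect_stack_events <- function(stack, roi = NULL, window, amp_threshold) {
  .assert(inherits(stack, "thermal_stack"), "`stack` must be a thermal_stack")
  roi <- roi %||% roi_from_max_projection(stack)
  cols <- seq(roi$col[1], roi$col[2])
  rows <- seq(roi$row[1], roi$row[2])
  det <- list()
  for (cc in cols) {
    for (rr in rows) {
      pk <- detect_trace_peaks(stack$frames[rr, cc, ], stack$f_rate,
                               window, amp_threshold)
      if (nrow(pk)) det[[length(det) + 1]] <- cbind(col = cc, row = rr, pk)
    }
  }
  empty <- data.frame(col = integer(0), row = integer(0), frame = integer(0),
                      time = numeric(0), amplitude = numeric(0),
                      width_s = numeric(0), n_pixels = integer(0))
  if (length(det) == 0) return(empty)
  det <- do.call(rbind, det)
  # union-find over detections: same pulse if frames differ by <= 1 and
  # pixels are 8-connected
  n <- nrow(det)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ord <- order(det$frame)
  det <- det[ord, , drop = FALSE]
  for (a in seq_len(n - 1)) {
    b <- a + 1
    while (b <= n && det$frame[b] - det$frame[a] <= 1) {
      if (abs(det$col[a] - det$col[b]) <= 1 && abs(det$row[a] - det$row[b]) <= 1) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
      b <- b + 1
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  events <- lapply(split(seq_len(n), comp), function(idx) {
    g <- det[idx, , drop = FALSE]
    rep_row <- g[which.max(g$amplitude), , drop = FALSE]
    rep_row$n_pixels <- nrow(g)
    rep_row
  })
  events <- do.call(rbind, events)
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  events
}

#' Export detected events as CSV
#'
#' @param events data frame from [detect_stack_events()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}
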