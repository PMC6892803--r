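test_that("flat NETD-noise traces produce almost no false positives", {
  # 100 seeded repeats of 500 flat frames at threshold 3 * NETD
  nfp <- 0
  set.seed(99)
  for (r in 1:100) {
    nfp <- nfp + nrow(detect_trace_peaks(20 + rnorm(500, 0, 0.1), 30, 18, 0.3))
  }
  expect_lt(nfp / 5e4, 1 / 1e4)
})

test_that("a clean synthetic bump is found at the time of its true maximum", {
  m <- make_uniform_square(800, 5)
  cam <- camera_model(format = c(9, 9))
  sm <- calibrate_amplitude(m, sample_ink(), test_beam(), cam, c(800, 800), 0.3, 2)
  ev <- data.frame(x0 = 800, y0 = 800, t0 = 5.0, duration = 0.3)
  st <- render_stack(m, sm, test_beam(), ev, cam, duration = 8, noise = "none")
  tr <- st$frames[5, 5, ]
  pk <- detect_trace_peaks(tr, 30, 18, 0.3)
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$time - (which.max(tr) - 1) / 30), 1.5 / 30)
  # two bumps 10 s apart are reported separately, in time order
  ev2 <- data.frame(x0 = 800, y0 = 800, t0 = c(2, 12), duration = 0.3)
  st2 <- render_stack(m, sm, test_beam(), ev2, cam, duration = 16, noise = "none")
  pk2 <- detect_trace_peaks(st2$frames[5, 5, ], 30, 18, 0.3)
  expect_equal(nrow(pk2), 2)
  expect_lt(abs(pk2$time[1] - 2.3), 0.1)
  expect_lt(abs(pk2$time[2] - 12.3), 0.1)
})

test_that("detection is translation-equivariant in time", {
  m <- make_uniform_square(800, 5)
  cam <- camera_model(format = c(9, 9))
  sm <- calibrate_amplitude(m, sample_ink(), test_beam(), cam, c(800, 800), 0.3, 2)
  ev <- data.frame(x0 = 800, y0 = 800, t0 = 3, duration = 0.3)
  st <- render_stack(m, sm, test_beam(), ev, cam, duration = 10, noise = "none")
  tr <- st$frames[5, 5, ]
  k <- 37
  shifted <- c(rep(tr[1], k), tr[1:(length(tr) - k)])
  p0 <- detect_trace_peaks(tr, 30, 18, 0.3)
  p1 <- detect_trace_peaks(shifted, 30, 18, 0.3)
  expect_equal(p1$time, p0$time + k / 30)
})

test_that("trace preconditions are enforced", {
  expect_error(detect_trace_peaks(c(1, NA, 3), 30, 18, 0.3), "finite")
  expect_error(detect_trace_peaks(rnorm(100), 30, 4, 0.3), "window")
  expect_error(detect_trace_peaks(rnorm(10), 30, 18, 0.3), "shorter")
})

test_that("clean stack detection counts the events landing on absorbers", {
  sc <- disk_scene()
  st <- disk_stack("none")
  ev <- quiet_detect(st, window = 18, amp_threshold = 0.3)
  expect_equal(nrow(ev), sum(sc$on_disk))               # exactly one per disk
  # one-to-one mapping between detections and scheduled absorbing events
  hits <- sc$schedule[sc$on_disk, ]
  matches <- vapply(hits$t0, function(tt) {
    sum(abs(ev$time - (tt + 0.3)) < 0.3 + 2 / 30)
  }, numeric(1))
  expect_true(all(matches == 1))
})

test_that("single simulated pulse at high SNR yields exactly one event", {
  m <- make_uniform_square(800, 5)
  cam <- test_camera()
  sm <- calibrate_amplitude(m, sample_ink(), test_beam(), cam, c(800, 800), 0.3, 2)
  ev <- data.frame(x0 = 800, y0 = 800, t0 = 1, duration = 0.3)
  st <- render_stack(m, sm, test_beam(), ev, cam, duration = 3, noise = "none")
  det <- quiet_detect(st, window = 18, amp_threshold = 0.3)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$time - 1.3), 0.1)
})

test_that("detection recall on disk targets is >= 0.99 under NETD noise", {
  sc <- disk_scene()
  hits_t <- sc$schedule$t0[sc$on_disk]
  total <- 0; found <- 0
  for (sd_ in 1:5) {
    st <- disk_stack("netd", sd_)
    ev <- quiet_detect(st, window = 18, amp_threshold = 0.3)
    found <- found + sum(vapply(hits_t, function(tt) {
      any(abs(ev$time - (tt + 0.3)) < 0.3 + 2 / 30)
    }, logical(1)))
    total <- total + length(hits_t)
  }
  expect_gte(found / total, 0.99)
})

test_that("the max-projection ROI brackets the active area", {
  # zero-absorptance stack: full frame with a warning
  m0 <- absorber_map(matrix(0, 40, 40), 10)
  ev <- data.frame(x0 = 200, y0 = 200, t0 = 0, duration = 0.3)
  cam <- camera_model(format = c(7, 5))
  st0 <- render_stack(m0, sample_ink(), test_beam(), ev, cam, duration = 1,
                      noise = "none")
  expect_warning(roi <- roi_from_max_projection(st0), "full frame")
  expect_equal(roi$col, c(1L, 7L))
  expect_equal(roi$row, c(1L, 5L))
  # single hot pixel: 5 x 5 padded box
  fr <- array(20, dim = c(9, 11, 4))
  fr[5, 6, 2] <- 22
  st1 <- thermal_stack(fr, 30, 400)
  roi1 <- roi_from_max_projection(st1, netd = 0.1)
  expect_equal(roi1$col, c(4L, 8L))
  expect_equal(roi1$row, c(3L, 7L))
  # simulated scan: the ROI box contains every event position
  sc <- disk_scene()
  st <- disk_stack("netd", 1)
  roi2 <- roi_from_max_projection(st)
  hits <- sc$schedule[sc$on_disk, ]
  cols <- ceiling((hits$x0 - st$origin[1]) / st$pixel_size)
  rows <- ceiling((hits$y0 - st$origin[2]) / st$pixel_size)
  expect_true(all(cols >= roi2$col[1] & cols <= roi2$col[2]))
  expect_true(all(rows >= roi2$row[1] & rows <= roi2$row[2]))
})
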