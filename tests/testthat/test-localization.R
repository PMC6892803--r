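# analytic Gaussian frame on the camera grid
gauss_frame <- function(x, y, xc, yc, zeta2, amp, off) {
  off + amp * exp(-outer((y - yc)^2, (x - xc)^2, `+`) / (2 * zeta2))
}

test_that("the two-step fit recovers a clean Gaussian peak exactly", {
  x <- seq(200, 4200, by = 400); y <- x
  z <- gauss_frame(x, y, xc = 2290, yc = 2120, zeta2 = 280^2, amp = 2, off = 19.85)
  loc <- fit_peak_two_step(z, x, y, zeta0_sq = 280^2)
  expect_true(loc$converged)
  expect_lt(abs(loc$x_c - 2290), 1e-3 * 400)
  expect_lt(abs(loc$y_c - 2120), 1e-3 * 400)
  expect_lt(abs(loc$dTmax - 2), 1e-3)
  expect_equal(loc$zeta2, 280^2, tolerance = 1e-4)
  expect_equal(loc$offset, 19.85, tolerance = 1e-5)
  # a misfit step-1 variance still centers the peak to a small fraction of
  # a pixel (a slight bias remains because the fit window is asymmetric
  # around the true center)
  loc2 <- fit_peak_two_step(z, x, y, zeta0_sq = 1.4 * 280^2)
  expect_lt(abs(loc2$x_c - 2290), 0.02 * 400)
  expect_equal(loc2$zeta2, 280^2, tolerance = 0.02)     # step 2 still recovers it
})

test_that("single-step models nest as expected on symmetric data", {
  x <- seq(200, 4200, by = 400); y <- x
  z <- gauss_frame(x, y, 2250, 2200, 270^2, 1.5, 19.85)
  fs <- fit_peak_single(z, x, y, "symmetric", zeta0_sq = 270^2)
  fa <- fit_peak_single(z, x, y, "asymmetric", zeta0_sq = 270^2)
  fk <- fit_peak_single(z, x, y, "skewed", zeta0_sq = 270^2)
  expect_true(fs$converged && fa$converged && fk$converged)
  expect_equal(fa$zeta_x2, fa$zeta_y2, tolerance = 1e-3)  # asymmetric collapses
  expect_lt(abs(fk$lambda_x), 0.05)                       # skew factors vanish
  expect_lt(abs(fk$lambda_y), 0.05)
  expect_lt(abs(fs$chi2red - fk$chi2red), 1e-6)
  expect_lt(abs(fs$x_c - 2250), 0.01)
})

test_that("predict_sigma matches its closed form and monotonicities", {
  expect_equal(predict_sigma(300, 400, 0, 100), sqrt((300^2 + 400^2 / 12) / 100))
  expect_equal(predict_sigma(300, 400, 5, 100),
               sqrt((300^2 + 400^2 / 12) / 100 +
                      4 * sqrt(pi) * 25 * 300^3 / (400 * 100^2)))
  n <- c(10, 50, 200, 1000, 1e6)
  expect_true(all(diff(predict_sigma(300, 400, 5, n)) < 0))  # decreasing in N
  expect_lt(predict_sigma(300, 400, 5, 1e9), 0.05)           # N -> Inf limit
  b <- c(0, 2, 5, 10)
  expect_true(all(diff(predict_sigma(300, 400, b, 100)) > 0))  # increasing in b
  expect_error(predict_sigma(300, 400, 5, 0), "n_photons")
})

test_that("sigma_vs_deltaT reproduces the calibrated-curve values", {
  expect_equal(sigma_vs_deltaT(599, 634, 0.9), sqrt(599 / 0.9 + 634 / 0.81))
  expect_equal(sigma_vs_deltaT(599, 634, 1), sqrt(1233))
  s <- sigma_vs_deltaT(599, 634, c(0.65, 0.75, 0.9))
  expect_true(all(s > 30 & s < 50))                     # the quoted uncertainty band
  expect_lt(sigma_vs_deltaT(599, 634, 1e6), 0.05)
  expect_error(sigma_vs_deltaT(599, 634, 0), "dT")
})

test_that("calibrate_alpha_beta recovers known coefficients", {
  dT <- c(0.5, 1, 2, 4, 8)
  sig <- sigma_vs_deltaT(599, 634, dT)
  cal <- calibrate_alpha_beta(dT, sig)
  expect_equal(cal$alpha, 599, tolerance = 1e-6)        # noise-free: exact
  expect_equal(cal$beta, 634, tolerance = 1e-6)
  set.seed(4)
  cal2 <- calibrate_alpha_beta(dT, sig * (1 + rnorm(5, 0, 0.05)))
  expect_lt(abs(cal2$alpha - 599), 3 * cal2$se_alpha)
  # beta = 0 truth: fitted beta not significantly positive
  sig0 <- sigma_vs_deltaT(599, 0, dT)
  set.seed(5)
  cal3 <- calibrate_alpha_beta(dT, sig0 * (1 + rnorm(5, 0, 0.02)))
  expect_true(cal3$beta <= 1.96 * cal3$se_beta + 1e-9)
  expect_error(calibrate_alpha_beta(c(1, 1, 1, 1), c(30, 31, 32, 33)), "degenerate")
  expect_error(calibrate_alpha_beta(c(1, 2), c(30, 20)), "4")
})

test_that("noise-free repeatability has zero center scatter", {
  s <- square_setup(target_dT = 2)
  r <- run_repeatability(s$map, s$sample, s$beam, s$camera, s$location,
                         n_pulses = 5, tau_on = s$tau_on, seed = 1,
                         models = "two_step", noise = "none")
  expect_lt(r$summary$sigma_x, 1e-4)
  expect_lt(r$summary$sigma_y, 1e-4)
  expect_equal(r$summary$dTmax, 2, tolerance = 1e-3)
})

test_that("overlapping pulses are rejected", {
  s <- square_setup()
  expect_error(
    run_repeatability(s$map, s$sample, s$beam, s$camera, s$location,
                      n_pulses = 5, tau_on = 0.3, seed = 1, spacing = 0.4),
    "overlap")
})

test_that("center scatter shrinks when the amplitude doubles", {
  s <- square_setup(target_dT = 1)
  lo <- run_repeatability(s$map, s$sample, s$beam, s$camera, s$location,
                          n_pulses = 60, tau_on = 0.3, seed = 2,
                          models = "two_step")
  s2 <- s$sample; s2$A <- s2$A * 2
  hi <- run_repeatability(s$map, s2, s$beam, s$camera, s$location,
                          n_pulses = 60, tau_on = 0.3, seed = 2,
                          models = "two_step")
  expect_lt(hi$summary$sigma_x, lo$summary$sigma_x)
  expect_lt(hi$summary$sigma_y, lo$summary$sigma_y)
})

test_that("localization of a uniform absorber is unbiased", {
  s <- square_setup(target_dT = 2)
  r <- run_repeatability(s$map, s$sample, s$beam, s$camera, s$location,
                         n_pulses = 100, tau_on = 0.3, seed = 6,
                         models = "two_step")
  f <- r$fits$two_step
  expect_lt(abs(mean(f$x_c) - 800), 3 * sd(f$x_c) / sqrt(nrow(f)))
  expect_lt(abs(mean(f$y_c) - 800), 3 * sd(f$y_c) / sqrt(nrow(f)))
})

test_that("a stripe edge shifts the center to the beam-weighted centroid", {
  # 30 um stripe half-covering the spot: the fitted center estimates the
  # beam-intensity-weighted centroid of the absorber, not the beam center
  map <- make_stripe_grid(30, 200, 1, pitch = 2.5, margin = 150, height = 600)
  beam <- test_beam(); cam <- test_camera()
  loc <- c(180, 300)                                    # beam parked at the stripe edge
  sm <- calibrate_amplitude(map, sample_ink(), beam, cam, c(165, 300), 0.3, 2)
  ax <- (seq_len(ncol(map$values)) - 0.5) * 2.5
  w <- exp(-2 * (ax - loc[1])^2 / beam$w0^2) * (map$values[120, ] > 0)
  x_oracle <- sum(ax * w) / sum(w)                      # numerical oracle
  r <- run_repeatability(map, sm, beam, cam, loc, n_pulses = 100, tau_on = 0.3,
                         seed = 3, models = "two_step")
  f <- r$fits$two_step
  n <- infer_photons_for_test(r, cam, sm)
  sig_pred <- predict_sigma(sqrt(mean(f$zeta2)), cam$pixel_size,
                            cam$background, n)
  expect_lt(abs(mean(f$x_c) - x_oracle), 1.3 * sig_pred)
  expect_lt(abs(x_oracle - loc[1]), 15)                 # centroid is inside the stripe
  expect_lt(x_oracle, loc[1])                           # shift toward the absorber
  expect_lt(mean(f$x_c), loc[1])
})

test_that("localize_events maps camera pixels to lab-frame centers", {
  m <- make_uniform_square(800, 5)
  cam <- test_camera()
  sm <- calibrate_amplitude(m, sample_ink(), test_beam(), cam, c(800, 800), 0.3, 2)
  ev <- data.frame(x0 = 800, y0 = 800, t0 = 1, duration = 0.3)
  st <- render_stack(m, sm, test_beam(), ev, cam, duration = 3, noise = "none")
  det <- quiet_detect(st, window = 18, amp_threshold = 0.3)
  locs <- localize_events(st, det, default_zeta0_sq(sm, test_beam(), cam, 0.3),
                          sample = sm)
  expect_equal(nrow(locs), 1)
  expect_lt(abs(locs$x_c - 800), 2)
  expect_lt(abs(locs$y_c - 800), 2)
  expect_equal(locs$dTmax, 2, tolerance = 0.01)
  expect_true(is.finite(locs$sigma_x))                  # closed-form sigma attached
  # empirical-law attachment path
  locs2 <- localize_events(st, det, default_zeta0_sq(sm, test_beam(), cam, 0.3),
                           uncertainty = c(599, 634))
  expect_equal(locs2$sigma_x, sigma_vs_deltaT(599, 634, locs2$dTmax))
})

test_that("calibrate_amplitude hits the requested camera amplitude", {
  m <- make_uniform_square(800, 5)
  cam <- test_camera()
  sm <- calibrate_amplitude(m, sample_ink(), test_beam(), cam, c(800, 800),
                            0.3, target_dT = 1.7)
  sched <- data.frame(x0 = 800, y0 = 800, t0 = 0, duration = 0.3)
  st <- render_stack(m, sm, test_beam(), sched, cam, duration = 0.35, noise = "none")
  pk <- max(st$frames) - sm$T0
  expect_equal(pk, 1.7, tolerance = 0.01)
  expect_error(calibrate_amplitude(absorber_map(matrix(0, 80, 80), 10),
                                   sample_ink(), test_beam(), cam,
                                   c(400, 400), 0.3, 1), "absorbing")
})
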