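test_that("gray-body radiance follows the Stefan-Boltzmann law", {
  expect_equal(radiance(19.85, 1), 5.67e-8 * 293^4)     # 417.88 W m^-2
  expect_equal(radiance(36.85, 0.95), 0.95 * 5.67e-8 * 310^4)
  expect_equal(radiance(50, 0), 0)
  expect_error(radiance(-300, 1), "absolute zero")
  expect_error(radiance(20, 1.5), "emissivity")
})

test_that("the linearized photon law underestimates by the known fractions", {
  # exact closed forms evaluated in integer arithmetic:
  # 295^4 - 293^4 = 203299824, 4 * 293^3 * 2 = 201230056
  expect_equal(photon_linearization_error(293, 2), 1 - 201230056 / 203299824)
  expect_equal(round(100 * photon_linearization_error(293, 2)), 1)
  # 303^4 - 293^4 = 1058841680, 4 * 293^3 * 10 = 1006150280
  expect_equal(photon_linearization_error(293, 10), 1 - 1006150280 / 1058841680)
  expect_lte(photon_linearization_error(293, 10), 0.05)
  expect_equal(photon_linearization_error(293, 0), 0)   # dT -> 0 limit
  expect_error(photon_linearization_error(-1, 2), "T0")
})

test_that("temperature_field vanishes without absorbers and before the pulse", {
  m0 <- absorber_map(matrix(0, 50, 50), 10)
  ev <- data.frame(x0 = 250, y0 = 250, t0 = 1, duration = 0.3)
  tf <- temperature_field(m0, sample_ink(), test_beam(), ev,
                          points = rbind(c(250, 250)), times = c(0.5, 2))
  expect_equal(as.vector(tf), c(0, 0))
  m1 <- make_uniform_square(500, 5)
  tf1 <- temperature_field(m1, sample_ink(), test_beam(), ev,
                           points = rbind(c(500, 500)), times = 0.5)
  expect_equal(tf1[1, 1], 0)                            # query before the pulse
})

test_that("the no-diffusion limits reproduce the closed forms", {
  m <- make_uniform_square(500, 5)
  beam <- test_beam()
  ev <- data.frame(x0 = 500, y0 = 500, t0 = 0, duration = 0.3)
  # D = 0, no loss: linear rise A * abar * t; profile exactly the beam Gaussian
  s_free <- sample_model(0.8, 0, A = 2, tau_d = 1e9)
  pts <- rbind(c(500, 500), c(511, 500), c(500, 489))
  tf <- temperature_field(m, s_free, beam, ev, pts, times = c(0.15, 0.3))
  expect_equal(tf[1, ], c(0.3, 0.6), tolerance = 1e-6)
  expect_equal(tf[2, 2], 0.6 * exp(-2 * 11^2 / 11^2), tolerance = 1e-6)
  expect_equal(tf[3, 2], tf[2, 2], tolerance = 1e-6)    # isotropy
  # D = 0, finite tau_d: saturating rise, exponential decay
  s_loss <- sample_model(0.8, 0, A = 2, tau_d = 0.2)
  tf2 <- temperature_field(m, s_loss, beam, ev, rbind(c(500, 500)),
                           times = c(0.3, 0.5))
  expect_equal(tf2[1, 1], 2 * 0.2 * (1 - exp(-0.3 / 0.2)), tolerance = 1e-3)
  expect_equal(tf2[1, 2], tf2[1, 1] * exp(-0.2 / 0.2), tolerance = 1e-3)
})

test_that("the field rises monotonically during the pulse and decays after", {
  m <- make_uniform_square(500, 5)
  ev <- data.frame(x0 = 500, y0 = 500, t0 = 0, duration = 0.3)
  times <- seq(0.03, 1.2, by = 0.03)
  tf <- temperature_field(m, sample_ink(), test_beam(), ev,
                          rbind(c(500, 500), c(530, 470)), times)
  for (r in 1:2) {
    rising <- times <= 0.3 + 1e-9
    expect_true(all(diff(tf[r, rising]) > 0))
    expect_true(all(diff(tf[r, !rising]) < 0))
  }
  # the maximum is at the end of the pulse
  expect_equal(which.max(tf[1, ]), max(which(times <= 0.3 + 1e-9)))
})

test_that("the field is linear in the heating amplitude", {
  m <- make_uniform_square(500, 5)
  ev <- data.frame(x0 = 500, y0 = 500, t0 = 0, duration = 0.3)
  t1 <- temperature_field(m, sample_ink(A = 1000), test_beam(), ev,
                          rbind(c(500, 500), c(520, 520)), c(0.2, 0.4))
  t2 <- temperature_field(m, sample_ink(A = 2000), test_beam(), ev,
                          rbind(c(500, 500), c(520, 520)), c(0.2, 0.4))
  expect_equal(t2, 2 * t1, tolerance = 1e-12)
})

test_that("doubling a short tau_on doubles the peak within 5%", {
  # regime: 8 D tau_on << w0^2 and tau_on << tau_d
  m <- make_uniform_square(500, 5)
  s <- sample_model(0.8, diffusivity = 100, A = 50, tau_d = 10)
  beam <- test_beam()
  f <- function(tau) {
    ev <- data.frame(x0 = 500, y0 = 500, t0 = 0, duration = tau)
    temperature_field(m, s, beam, ev, rbind(c(500, 500)), tau)[1, 1]
  }
  expect_equal(f(0.04) / f(0.02), 2, tolerance = 0.05)
})

test_that("a symmetric Gaussian describes the spot while 8 D tau_on <~ w0^2", {
  m <- make_uniform_square(500, 2.5)
  beam <- test_beam()                                    # w0 = 11 um
  s <- sample_model(0.8, diffusivity = 121 / (8 * 0.3), A = 100, tau_d = 1)
  ev <- data.frame(x0 = 500, y0 = 500, t0 = 0, duration = 0.3)
  g <- seq(460, 540, by = 4)
  pts <- as.matrix(expand.grid(x = g, y = g))
  z <- matrix(temperature_field(m, s, beam, ev, pts, 0.3), length(g), length(g))
  fit <- fit_peak_single(t(z), g, g, "symmetric", zeta0_sq = 121)
  expect_true(fit$converged)
  model <- fit$offset + fit$dTmax *
    exp(-outer((g - fit$y_c)^2, (g - fit$x_c)^2, `+`) / (2 * fit$zeta2))
  expect_lt(max(abs(t(z) - model)) / max(z), 0.02)
})

test_that("clean stacks reproduce the baseline and the event location", {
  m0 <- absorber_map(matrix(0, 40, 40), 10)
  ev <- data.frame(x0 = 200, y0 = 200, t0 = 0.2, duration = 0.3)
  cam <- camera_model(format = c(6, 6))
  st <- render_stack(m0, sample_ink(), test_beam(), ev, cam, duration = 1,
                     noise = "none")
  expect_true(all(st$frames == sample_ink()$T0))
  # single event on an absorber: global max in the pixel containing (x0, y0)
  m <- make_uniform_square(800, 5)
  ev2 <- data.frame(x0 = 800, y0 = 800, t0 = 0.2, duration = 0.3)
  st2 <- render_stack(m, sample_ink(), test_beam(), ev2, test_camera(),
                      duration = 1.5, noise = "none")
  peak <- which(st2$frames == max(st2$frames), arr.ind = TRUE)[1, ]
  xs <- st2$origin[1] + (peak[2] - 0.5) * 400
  ys <- st2$origin[2] + (peak[1] - 0.5) * 400
  expect_lt(abs(xs - 800), 200)
  expect_lt(abs(ys - 800), 200)
  ts <- (peak[3] - 1) / 30
  expect_lt(abs(ts - 0.5), 1.5 / 30)                    # peak frame near t0 + tau_on
})

test_that("rendered amplitude is linear in A (noise off)", {
  m <- make_uniform_square(800, 5)
  ev <- data.frame(x0 = 800, y0 = 800, t0 = 0, duration = 0.3)
  r1 <- render_stack(m, sample_ink(A = 1000), test_beam(), ev, test_camera(),
                     duration = 0.4, noise = "none")
  r2 <- render_stack(m, sample_ink(A = 2000), test_beam(), ev, test_camera(),
                     duration = 0.4, noise = "none")
  expect_equal(r2$frames - 19.85, 2 * (r1$frames - 19.85), tolerance = 1e-9)
})

test_that("NETD noise has the stated per-pixel statistics", {
  m0 <- absorber_map(matrix(0, 40, 40), 10)
  ev <- data.frame(x0 = 200, y0 = 200, t0 = 0, duration = 0.3)
  cam <- camera_model(format = c(6, 6))
  st <- render_stack(m0, sample_ink(), test_beam(), ev, cam, duration = 20,
                     noise = "netd", seed = 3)
  expect_gte(dim(st)[3], 500)
  sds <- apply(st$frames, c(1, 2), sd)
  expect_true(all(abs(sds - 0.1) < 0.012))              # within 10% of NETD
})

test_that("stochastic rendering is seed-deterministic", {
  m <- make_uniform_square(800, 5)
  ev <- data.frame(x0 = 800, y0 = 800, t0 = 0, duration = 0.3)
  a <- render_stack(m, sample_ink(A = 5000), test_beam(), ev, test_camera(),
                    duration = 0.5, noise = "photon", seed = 11)
  b <- render_stack(m, sample_ink(A = 5000), test_beam(), ev, test_camera(),
                    duration = 0.5, noise = "photon", seed = 11)
  d <- render_stack(m, sample_ink(A = 5000), test_beam(), ev, test_camera(),
                    duration = 0.5, noise = "photon", seed = 12)
  expect_identical(a$frames, b$frames)
  expect_false(identical(a$frames, d$frames))
  expect_error(render_stack(m, sample_ink(), test_beam(), ev, test_camera(),
                            duration = 0.5, noise = "photon"), "seed")
})

test_that("photon noise scales with the linearized gray-body signal", {
  m0 <- absorber_map(matrix(0, 40, 40), 10)
  ev <- data.frame(x0 = 200, y0 = 200, t0 = 0, duration = 0.1)
  cam <- camera_model(format = c(5, 5))
  sm <- sample_ink()
  st <- render_stack(m0, sm, test_beam(), ev, cam, duration = 40,
                     noise = "photon", seed = 8)
  gain <- cam$photon_gain * 4 * sm$emissivity * 5.67e-8 * (sm$T0 + 273.15)^3
  expect_equal(mean(st$frames), sm$T0, tolerance = 0.01)
  expect_equal(sd(st$frames), sqrt(cam$background) / gain, tolerance = 0.05)
})

test_that("a duration shorter than the schedule warns and truncates", {
  m <- make_uniform_square(800, 5)
  ev <- data.frame(x0 = 800, y0 = 800, t0 = c(0, 2), duration = 0.3)
  expect_warning(
    st <- render_stack(m, sample_ink(), test_beam(), ev, test_camera(),
                       duration = 1, noise = "none"),
    "truncated")
  expect_lte(dim(st)[3], 31)
})
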