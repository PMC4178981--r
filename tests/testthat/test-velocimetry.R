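cfg75 <- acquisition_config(35e6, 250e6, 3e3, c = 1540, doppler_angle = 75,
                            tx_cycles = 7, fractional_bandwidth = 0.55,
                            n_fast = 16, n_slow = 2)

test_that("the Doppler equation and its inverse agree with closed forms", {
  expect_identical(doppler_to_velocity(0, cfg75), 0)
  # -235.3 Hz at 35 MHz / 75 degrees / 1540 m/s -> -20.0 mm/s
  expect_equal(doppler_to_velocity(-235.3, cfg75), -0.0200008465,
               tolerance = 1e-8)
  set.seed(9)
  v <- runif(100, -0.2, 0.2)
  expect_equal(doppler_to_velocity(velocity_to_doppler(v, cfg75), cfg75), v,
               tolerance = 1e-12)
  near90 <- acquisition_config(35e6, 250e6, 3e3, doppler_angle = 89.9999999,
                               n_fast = 16, n_slow = 2)
  expect_error(doppler_to_velocity(100, near90), "angle correction undefined")
})

test_that("the Nyquist velocity follows prf * c / (4 f0 cos(theta))", {
  expect_equal(nyquist_velocity(cfg75), 0.1275022091,
               tolerance = 1e-8)
  cfg0 <- acquisition_config(35e6, 250e6, 3e3, doppler_angle = 0,
                             n_fast = 16, n_slow = 2)
  expect_equal(nyquist_velocity(cfg0), 3e3 * 1540 / (4 * 35e6))
  cfg2 <- acquisition_config(35e6, 250e6, 6e3, doppler_angle = 0,
                             n_fast = 16, n_slow = 2)
  expect_equal(nyquist_velocity(cfg2), 2 * nyquist_velocity(cfg0))
})

test_that("estimate_doppler reads peaks, envelope edges, and noise", {
  freq <- seq(-1400, 1400, by = 100)
  col <- rep(-50, length(freq))
  col[freq == -200] <- 0
  expect_equal(estimate_doppler(col, freq, "peak"), -200)
  expect_equal(estimate_doppler(col, freq, "max_envelope"), -200)
  # broadened spectrum: the envelope edge exceeds the mode in |f|
  col2 <- rep(-50, length(freq))
  col2[freq == -200] <- 0
  col2[freq == -300] <- -6
  expect_equal(estimate_doppler(col2, freq, "peak"), -200)
  edge <- estimate_doppler(col2, freq, "max_envelope")
  expect_equal(edge, -300)
  expect_gt(abs(edge), abs(estimate_doppler(col2, freq, "peak")))
  # a flat column is flagged below noise
  flat <- sin(seq_along(freq)) * 3 - 3
  expect_true(is.na(estimate_doppler(flat, freq)))
  expect_true(attr(estimate_doppler(flat, freq), "below_noise"))
  expect_error(estimate_doppler(numeric(0), numeric(0)), "empty")
})

test_that("the broadening inversion undoes the forward edge model", {
  beta <- transit_beta_for_test(0.55)
  gamma <- sqrt(2 * log(10^(12 / 20)))
  for (f in c(100, 235, 1176, 4000)) {
    for (sw in c(20, 58, 120)) {
      edge <- f + gamma * sqrt((beta * f)^2 + sw^2)
      est <- pwdoppler:::invert_broadening(edge, beta, sw, 12)
      expect_equal(est, f, tolerance = 1e-9)
    }
  }
  # an edge inside the window's own width collapses to zero, not negative
  expect_identical(pwdoppler:::invert_broadening(10, beta, 58, 12), 0)
})

test_that("trapezoidal displacement matches closed forms", {
  # constant velocity: d(T) = v T exactly
  t <- seq(0, 2, by = 0.01)
  d <- integrate_displacement(t, rep(3e-3, length(t)))
  expect_identical(d$displacement[1], 0)
  expect_equal(d$displacement[length(t)], 3e-3 * 2, tolerance = 1e-12)
  # sinusoidal velocity: d(t) = (V / 2 pi f) sin(2 pi f t) within the
  # trapezoid error bound (2 pi f dt)^2 * V / (2 pi f)
  V <- 1e-3; fw <- 2; dt <- 0.005
  t2 <- seq(0, 1, by = dt)
  d2 <- integrate_displacement(t2, V * cos(2 * pi * fw * t2))
  bound <- (2 * pi * fw * dt)^2 * V / (2 * pi * fw)
  expect_lt(max(abs(d2$displacement - V / (2 * pi * fw) *
                    sin(2 * pi * fw * t2))), bound)
  # one symmetric sign-reversing cycle nets ~ zero
  t3 <- seq(0, 0.5, by = 1e-3)
  d3 <- integrate_displacement(t3, V * sin(2 * pi * 2 * t3))
  expect_lt(abs(d3$displacement[length(t3)]), 1e-3 * V)
  expect_error(integrate_displacement(c(0, 2, 1), c(1, 1, 1)),
               "strictly increasing")
  expect_error(integrate_displacement(c(0, 1), c(1, NA)), "non-finite")
})

test_that("gate_displacement interpolates interior masked slots", {
  times <- seq(0, 1, by = 0.1)
  v <- sin(2 * pi * times)
  vm <- v; vm[5] <- NA
  prof <- structure(list(depths = 1e-3, times = times,
                         velocity = matrix(vm, 1), mask = matrix(is.na(vm), 1),
                         mode = "peak", config = cfg75),
                    class = "velocity_profile")
  d <- gate_displacement(prof, 1)
  ref <- integrate_displacement(times, v)
  expect_lt(max(abs(d$displacement - ref$displacement)), 0.02)
})

test_that("speeds beyond the Nyquist velocity wrap in the spectrum", {
  cfg <- acquisition_config(35e6, 250e6, 2e3, c = 1540, doppler_angle = 0,
                            tx_cycles = 7, fractional_bandwidth = 0.55,
                            n_fast = 2300, n_slow = 256)
  v_true <- 25e-3                       # f_d = -1136 Hz, beyond prf/2 = 1 kHz
  expect_gt(v_true, nyquist_velocity(cfg))
  mot <- motion_translation(v_true, 3e-3)
  fld <- make_field(mot, cfg)
  ens <- suppressWarnings(simulate_ensemble(fld, mot, cfg, noise_db = -Inf,
                                            seed = 2))
  an <- demodulate(ens)
  mid <- 3e-3 + v_true * (255 / 2e3) / 2
  g <- extract_gates(an, gate_spec(depths = mid))
  S <- Mod(fft(g$signals[1, ]))
  k <- which.max(S) - 1
  f <- (if (k >= 128) k - 256 else k) * 2e3 / 256
  wrapped <- -2 * v_true * 35e6 / 1540 + 2e3   # aliased up by one prf
  expect_lt(abs(f - wrapped), 3 * 2e3 / 256)
})
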