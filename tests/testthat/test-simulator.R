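test_that("the transmit pulse has the stated length and unit peak", {
  p <- synth_pulse(pulse_spec(35e6, 7, 0.55), 250e6)
  expect_length(p, 50)  # round(250e6 * 7 / 35e6)
  # one cycle, very wide band: a single dominant lobe with peak exactly 1
  p1 <- synth_pulse(pulse_spec(35e6, 1, 1.9), 250e6)
  expect_identical(max(abs(p1)), 1)
  expect_lt(sum(abs(p1) > 0.5), 5)
  expect_error(synth_pulse(pulse_spec(35e6, 7, 0.55), 60e6), "alias")
})

test_that("the pulse's measured -6 dB spectral width matches the bandwidth", {
  f0 <- 35e6; fs <- 250e6; bw <- 0.55
  p <- synth_pulse(pulse_spec(f0, 7, bw), fs)
  nfft <- 2^16
  S <- Mod(fft(c(p, rep(0, nfft - length(p)))))[1:(nfft / 2)]
  f <- (0:(nfft / 2 - 1)) * fs / nfft
  thr <- max(S) * 10^(-6 / 20)
  width <- diff(range(f[S >= thr]))
  expect_lt(abs(width - bw * f0) / (bw * f0), 0.05)
})

test_that("scatterer fields honour the motion variant and are deterministic", {
  cfg <- acquisition_config(35e6, 250e6, 10e3, doppler_angle = 75,
                            tx_cycles = 7, fractional_bandwidth = 0.55,
                            n_fast = 3500, n_slow = 16)
  f1 <- make_field(motion_translation(20e-3, 7.3e-3), cfg)
  expect_identical(nrow(f1), 1L)
  expect_equal(f1$depth, 7.3e-3)

  mot <- motion_parabolic_flow(7e-3, 4.5e-3, 100e-3)
  ff <- make_field(mot, cfg, density = 20, seed = 3)
  expect_identical(nrow(ff), 90L)  # round(20 / mm * 4.5 mm)
  expect_true(all(abs(ff$r) <= 2.25e-3))
  expect_identical(ff, make_field(mot, cfg, density = 20, seed = 3))

  # vessel extending beyond the representable depth range is rejected
  deep <- motion_parabolic_flow(10e-3, 4.5e-3, 100e-3)
  expect_error(make_field(deep, cfg, density = 20, seed = 3), "beyond")
})

test_that("a static field yields identical echo lines before noise", {
  fx <- tiny_reflector(speed = 0, n_slow = 8)
  E <- fx$ensemble$samples
  for (n in 2:nrow(E)) expect_identical(E[n, ], E[1, ])
  expect_gt(max(abs(E)), 0.5)
})

test_that("the inter-pulse echo shift matches the range-equation delay", {
  # 20 mm/s at 75 degrees, prf 3 kHz: delay shift 2*v*cos(75)/(c*prf)
  # ~ 2.24 ns/pulse; accumulated over 100 pulses at 250 MSPS that is 56
  # samples, measured by brute-force cross-correlation of the echo lines.
  fx <- tiny_reflector(n_slow = 101L, n_fast = 2300L, doppler_angle = 75,
                       speed = 20e-3, depth = 4e-3)
  e1 <- fx$ensemble$samples[1, ]
  e101 <- fx$ensemble$samples[101, ]
  lags <- -80:80
  cc <- vapply(lags, function(l) {
    i <- seq_along(e1)
    j <- i + l
    ok <- j >= 1 & j <= length(e1)
    sum(e1[i[ok]] * e101[j[ok]])
  }, numeric(1))
  expected <- round(100 * 2 * 20e-3 * cos(75 * pi / 180) / (1540 * 3e3) * 250e6)
  expect_identical(expected, 56)
  expect_equal(lags[which.max(cc)], expected, tolerance = 0.02)
})

test_that("injected noise matches noise_db measured on signal-free samples", {
  quiet <- tiny_reflector(depth = 2e-3, n_fast = 2000, n_slow = 32,
                          speed = 0, noise_db = -Inf)
  noisy <- simulate_ensemble(quiet$field, quiet$motion, quiet$cfg,
                             noise_db = -20, seed = 99)
  sig_rms <- sqrt(mean(quiet$ensemble$samples^2))
  free <- 1000:2000  # well beyond the echo at 2 mm (sample ~650)
  measured <- sd(noisy$samples[, free])
  expect_lt(abs(20 * log10(measured / sig_rms) - (-20)), 1)
})

test_that("the simulator is deterministic given identical seeds", {
  a <- tiny_reflector(noise_db = -25, seed = 4L)
  b <- tiny_reflector(noise_db = -25, seed = 4L)
  expect_identical(a$ensemble$samples, b$ensemble$samples)
})

test_that("the parabolic speed field is v_max at the centre, 0 at the wall", {
  mot <- motion_parabolic_flow(7e-3, 4.5e-3, 100e-3)
  expect_equal(true_velocity(mot, 7e-3), -100e-3)
  expect_equal(true_velocity(mot, 7e-3 + 2.25e-3), 0)
  expect_equal(true_velocity(mot, 7e-3 - 2.25e-3), 0)
  expect_true(is.na(true_velocity(mot, 1e-3)))
})

test_that("super-Nyquist axial speeds raise an aliasing warning", {
  cfg <- acquisition_config(35e6, 250e6, 1e3, doppler_angle = 0,
                            tx_cycles = 7, fractional_bandwidth = 0.55,
                            n_fast = 2000, n_slow = 16)
  mot <- motion_translation(speed = 15e-3, depth = 3e-3)  # f_d ~ 682 Hz
  fld <- make_field(mot, cfg)
  expect_warning(simulate_ensemble(fld, mot, cfg, noise_db = -Inf, seed = 1),
                 "aliasing")
})
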