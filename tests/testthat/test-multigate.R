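test_that("the pulse-echo range equation maps depth to sample index", {
  cfg <- acquisition_config(35e6, 250e6, 3e3, n_fast = 3000, n_slow = 2)
  expect_identical(depth_to_sample(0, cfg), 0L)
  expect_identical(depth_to_sample(7.3e-3, cfg), 2370L)  # round(2370.1)
  set.seed(3)
  d <- runif(100, 0, max_depth(cfg) * 0.999)
  expect_true(all(abs(sample_to_depth(depth_to_sample(d, cfg), cfg) - d) <=
                  cfg$c / (4 * cfg$fs)))
  expect_error(depth_to_sample(1, cfg), "maximum representable depth")
})

test_that("gate specs validate their geometry", {
  expect_error(gate_spec(depths = c(2e-3, 1e-3)), "increasing")
  expect_error(gate_spec(depths = 1e-3, gate_length = 2), "odd")
  expect_error(gate_spec(), "exactly one")
  sp <- gate_span(4e-3, 10e-3, 0.25e-3)
  expect_length(sp$depths, 25)
})

test_that("gate_length 1 extracts the single complex sample per pulse", {
  cfg <- acquisition_config(35e6, 250e6, 3e3, n_fast = 64, n_slow = 5)
  set.seed(4)
  S <- matrix(complex(real = rnorm(5 * 64), imaginary = rnorm(5 * 64)), 5, 64)
  an <- analytic_ensemble(cfg, S)
  g <- extract_gates(an, gate_spec(indices = c(10L, 20L), gate_length = 1L))
  expect_equal(g$signals[1, ], S[, 11])
  expect_equal(g$signals[2, ], S[, 21])
  # a 12-gate spec yields 12 slow-time signals
  g12 <- extract_gates(an, gate_spec(indices = seq(5L, 60L, 5L)))
  expect_identical(dim(g12$signals), c(12L, 5L))
  expect_error(extract_gates(an, gate_spec(indices = 63L, gate_length = 5L)),
               "gate 1")
})

test_that("gate extraction is linear in the input ensemble", {
  cfg <- acquisition_config(35e6, 250e6, 3e3, n_fast = 48, n_slow = 6)
  sp <- gate_spec(indices = c(8L, 30L), gate_length = 3L)
  set.seed(5)
  for (rep in 1:3) {
    X <- matrix(complex(real = rnorm(6 * 48), imaginary = rnorm(6 * 48)), 6, 48)
    Y <- matrix(complex(real = rnorm(6 * 48), imaginary = rnorm(6 * 48)), 6, 48)
    a <- rnorm(1); b <- rnorm(1)
    gxy <- extract_gates(analytic_ensemble(cfg, a * X + b * Y), sp)$signals
    gx <- extract_gates(analytic_ensemble(cfg, X), sp)$signals
    gy <- extract_gates(analytic_ensemble(cfg, Y), sp)$signals
    expect_equal(gxy, a * gx + b * gy, tolerance = 1e-12)
  }
})

test_that("a constant-velocity scatterer dominates at its Doppler bin", {
  fx <- tiny_reflector(n_slow = 256, n_fast = 2300, doppler_angle = 0,
                       speed = 20e-3, depth = 4e-3)
  an <- demodulate(fx$ensemble)
  mid <- 4e-3 + 20e-3 * (255 / 3e3) / 2
  g <- extract_gates(an, gate_spec(depths = mid))
  S <- Mod(fft(g$signals[1, ]))
  k <- which.max(S) - 1
  f <- (if (k >= 256 / 2) k - 256 else k) * 3e3 / 256
  expected <- -2 * 20e-3 * 35e6 / 1540   # motion away: negative
  expect_lt(abs(f - expected), 3e3 / 256)
})

test_that("a signal-free gate carries the injected noise power", {
  fx <- tiny_reflector(depth = 2e-3, n_fast = 2000, n_slow = 64, speed = 0,
                       noise_db = -Inf)
  noisy <- simulate_ensemble(fx$field, fx$motion, fx$cfg, noise_db = -20,
                             seed = 12)
  sig_rms <- sqrt(mean(fx$ensemble$samples^2))
  sigma2 <- (sig_rms * 10^(-20 / 20))^2
  an <- demodulate(noisy, band = NULL)   # no band-pass: full noise band
  g <- extract_gates(an, gate_spec(depths = 5e-3))  # far from the echo
  # analytic signal of white noise has power 2 sigma^2
  ratio_db <- 10 * log10(mean(Mod(g$signals)^2) / (2 * sigma2))
  expect_lt(abs(ratio_db), 3)
})

test_that("the clutter filter rejects DC, passes 0.3 prf, and can be off", {
  cfg <- acquisition_config(35e6, 250e6, 10e3, n_fast = 16, n_slow = 1024)
  n <- 0:1023
  mk <- function(sig) gate_ensemble(cfg, gate_spec(indices = 0L),
                                    matrix(sig, 1))
  centre <- 300:700
  dc <- clutter_filter(mk(rep(1 + 1i, 1024)), cutoff = 200, mode = "highpass")
  expect_lt(max(Mod(dc$signals[1, centre])), 1e-2 * Mod(1 + 1i))

  tone <- mk(exp(2i * pi * 0.3 * n))
  hp <- clutter_filter(tone, cutoff = 0.02 * 1e4, mode = "highpass")
  expect_lt(max(abs(Mod(hp$signals[1, centre]) - 1)), 0.05)

  passthrough <- clutter_filter(tone, mode = "off")
  expect_identical(passthrough$signals, tone$signals)
  expect_error(clutter_filter(tone, cutoff = 6e3, mode = "highpass"),
               "prf/2")
})
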