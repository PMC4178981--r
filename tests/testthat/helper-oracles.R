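# Independent oracles and small fixture builders used across test files.

# Brute-force discrete Hilbert transform: periodic convolution with the
# ideal kernel, the kernel itself obtained by an O(n^2) manual inverse DFT
# of the -i*sign(frequency) multiplier (no stats::fft anywhere).
brute_hilbert <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  # -i on positive frequencies, +i on negative, 0 at DC (and Nyquist)
  H <- complex(real = 0, imaginary = 0) * k
  pos <- k >= 1 & k < n / 2
  neg <- k > n / 2
  H[pos] <- -1i
  H[neg] <- 1i
  m <- 0:(n - 1)
  kern <- vapply(m, function(mm)
    sum(H * exp(2i * pi * k * mm / n)) / n, complex(1))
  out <- vapply(m, function(j)
    sum(x * kern[((j - (0:(n - 1))) %% n) + 1]), complex(1))
  Re(out)
}

# Round a double vector to its float32 representation.
quantize32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
          n = length(x), size = 4L)
}

# Wrap phase increments into (-pi, pi].
wrap_phase <- function(d) ((d + pi) %% (2 * pi)) - pi

# Small reflector configuration used by several unit tests (kept tiny; the
# full-scale study conditions live in test-acceptance.R).
tiny_reflector <- function(n_slow = 64L, n_fast = 1536L, prf = 3e3,
                           doppler_angle = 0, speed = 20e-3, depth = 4e-3,
                           noise_db = -Inf, seed = 11L) {
  cfg <- acquisition_config(35e6, 250e6, prf, c = 1540,
                            doppler_angle = doppler_angle, tx_cycles = 7,
                            fractional_bandwidth = 0.55,
                            n_fast = n_fast, n_slow = n_slow, seed = seed)
  mot <- motion_translation(speed = speed, depth = depth)
  fld <- make_field(mot, cfg, seed = seed)
  list(cfg = cfg, motion = mot, field = fld,
       ensemble = simulate_ensemble(fld, mot, cfg, noise_db = noise_db,
                                    seed = seed + 1L))
}

quantize32_mat <- function(m) matrix(quantize32(m), nrow(m), ncol(m))

# Independent recomputation of the relative transit-broadening constant.
transit_beta_for_test <- function(bw) bw / (2 * sqrt(2 * log(10^(6 / 20))))
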