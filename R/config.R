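#' Acquisition configuration
#'
#' Bundles every physical and sampling parameter of a pulsed-wave Doppler
#' acquisition: the transmit carrier, the fast-time (depth) sampling rate, the
#' pulse repetition frequency that samples slow time, the assumed sound speed,
#' the beam-to-motion Doppler angle, and the transmit pulse description.
#'
#' Validity is enforced on construction:
#' * `f0 > 0` and `fs > 2 * f0 * (1 + fractional_bandwidth)` (fast-time
#'   Nyquist with margin for the pulse band edges),
#' * `prf > 0`, `c > 0`, `0 <= doppler_angle < 90`,
#' * `tx_cycles >= 1`, `0 < fractional_bandwidth < 2`,
#' * `n_fast >= 1`, `n_slow >= 1`.
#'
#' @param f0 carrier frequency, Hz.
#' @param fs fast-time sampling rate, Hz.
#' @param prf pulse repetition frequency, Hz.
#' @param c sound speed, m/s. Default 1540 (standard soft-tissue value; water
#'   is ~1480 — the chain is self-consistent for any fixed value, so state the
#'   one you analyse with).
#' @param doppler_angle beam-to-motion angle, degrees, in `[0, 90)`.
#' @param tx_cycles transmit cycles per pulse (integer >= 1).
#' @param fractional_bandwidth -6 dB fractional bandwidth of the (two-way)
#'   transducer response folded into the transmit pulse, dimensionless.
#' @param n_fast samples per pulse echo line.
#' @param n_slow number of pulses in the ensemble.
#' @param seed integer RNG seed (used by the simulator only; may be `NA`).
#'
#' @return An object of class `acquisition_config` (a validated list).
#' @examples
#' cfg <- acquisition_config(
#'   f0 = 35e6, fs = 250e6, prf = 3e3, doppler_angle = 75,
#'   tx_cycles = 7, fractional_bandwidth = 0.55, n_fast = 3072, n_slow = 1024
#' )
#' cfg$f0
#' @export
acquisition_config <- function(f0, fs, prf, c = 1540, doppler_angle = 0,
                               tx_cycles = 1L, fractional_bandwidth = 0.5,
                               n_fast = 1L, n_slow = 1L, seed = NA_integer_) {
  cfg <- list(
    f0 = as.numeric(f0), fs = as.numeric(fs), prf = as.numeric(prf),
    c = as.numeric(c), doppler_angle = as.numeric(doppler_angle),
    tx_cycles = as.integer(tx_cycles),
    fractional_bandwidth = as.numeric(fractional_bandwidth),
    n_fast = as.integer(n_fast), n_slow = as.integer(n_slow),
    seed = if (is.na(seed)) NA_integer_ else as.integer(seed)
  )
  class(cfg) <- "acquisition_config"
  validate_config(cfg)
  cfg
}

#' Validate an acquisition configuration
#'
#' Checks the invariants documented in [acquisition_config()]; stops with an
#' informative message on the first violation.
#'
#' @param cfg an `acquisition_config`.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "acquisition_config"))
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("config field '", nm, "' must be a single finite number", call. = FALSE)
  }
  for (nm in c("f0", "fs", "prf", "c", "doppler_angle", "fractional_bandwidth"))
    num1(cfg[[nm]], nm)
  if (cfg$f0 <= 0) stop("f0 must be > 0", call. = FALSE)
  if (cfg$prf <= 0) stop("prf must be > 0", call. = FALSE)
  if (cfg$c <= 0) stop("sound speed c must be > 0", call. = FALSE)
  if (cfg$doppler_angle < 0 || cfg$doppler_angle >= 90)
    stop("doppler_angle must lie in [0, 90) degrees, got ", cfg$doppler_angle,
         call. = FALSE)
  if (cfg$fractional_bandwidth <= 0 || cfg$fractional_bandwidth >= 2)
    stop("fractional_bandwidth must lie in (0, 2)", call. = FALSE)
  if (cfg$fs <= 2 * cfg$f0 * (1 + cfg$fractional_bandwidth))
    stop("fs = ", cfg$fs, " violates the fast-time Nyquist margin: need fs > ",
         "2 * f0 * (1 + fractional_bandwidth) = ",
         2 * cfg$f0 * (1 + cfg$fractional_bandwidth), call. = FALSE)
  if (is.na(cfg$tx_cycles) || cfg$tx_cycles < 1L)
    stop("tx_cycles must be an integer >= 1", call. = FALSE)
  if (is.na(cfg$n_fast) || cfg$n_fast < 1L) stop("n_fast must be >= 1", call. = FALSE)
  if (is.na(cfg$n_slow) || cfg$n_slow < 1L) stop("n_slow must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat("<acquisition_config>\n")
  cat(sprintf("  carrier f0        : %.3f MHz\n", x$f0 / 1e6))
  cat(sprintf("  fast-time fs      : %.1f MHz  (%d samples/line)\n",
              x$fs / 1e6, x$n_fast))
  cat(sprintf("  PRF               : %.3f kHz  (%d pulses)\n",
              x$prf / 1e3, x$n_slow))
  cat(sprintf("  sound speed       : %.0f m/s\n", x$c))
  cat(sprintf("  Doppler angle     : %.1f deg\n", x$doppler_angle))
  cat(sprintf("  pulse             : %d cycles, %.0f%% bandwidth\n",
              x$tx_cycles, 100 * x$fractional_bandwidth))
  cat(sprintf("  max depth         : %.2f mm\n", 1e3 * max_depth(x)))
  invisible(x)
}

#' Maximum representable depth
#'
#' The pulse-echo range equation maps fast-time sample `i` (0-based) to depth
#' `c * i / (2 * fs)`; the deepest representable depth (exclusive) is
#' `c * n_fast / (2 * fs)`.
#'
#' @param cfg an `acquisition_config`.
#' @return depth in metres (exclusive upper bound).
#' @export
max_depth <- function(cfg) cfg$c * cfg$n_fast / (2 * cfg$fs)

# Doppler angle in radians; cos(theta) projection used throughout.
cos_theta <- function(cfg) cos(cfg$doppler_angle * pi / 180)

# -6 dB Gaussian envelope time constant of the transmit pulse, seconds.
# Envelope exp(-t^2 / (2 sigma^2)) has magnitude spectrum
# exp(-2 pi^2 f^2 sigma^2); the -6 dB full spectral width equals
# fractional_bandwidth * f0 when sigma = 2*sqrt(2 ln 10^(6/20)) / (2 pi bw f0)
# = 1.17549 / (pi * bw * f0).
pulse_sigma_t <- function(f0, fractional_bandwidth) {
  k6 <- sqrt(2 * log(10^(6 / 20)))  # 1.17549...
  k6 / (pi * fractional_bandwidth * f0)
}

# Axial extent (std dev, metres) of the pulse envelope as seen by a gate:
# the echo from a point at depth offset dz is the envelope evaluated at
# 2*dz/c, so sigma_z = c * sigma_t / 2.
pulse_sigma_z <- function(cfg) cfg$c * pulse_sigma_t(cfg$f0, cfg$fractional_bandwidth) / 2
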