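#' Analytic ensemble: complex I/Q matrix from Hilbert demodulation
#'
#' Output of [demodulate()]: the complex analytic signal of each band-pass
#' filtered echo line. Writing the filtered RF line as
#' `x(t) = A(t) cos(theta(t))`, the real part is `x(t)` itself and the
#' imaginary part is its Hilbert transform `A(t) sin(theta(t))` (valid under
#' the Bedrosian condition: the envelope's spectrum lies below the
#' carrier's). The real part equals the band-pass output to machine
#' precision by construction.
#'
#' @param config the [acquisition_config()] carried through unchanged.
#' @param samples complex matrix `n_slow x n_fast`.
#' @return object of class `analytic_ensemble`.
#' @export
analytic_ensemble <- function(config, samples) {
  validate_config(config)
  if (!is.matrix(samples) || !is.complex(samples))
    stop("samples must be a complex matrix", call. = FALSE)
  if (nrow(samples) != config$n_slow || ncol(samples) != config$n_fast)
    stop("samples shape does not match config", call. = FALSE)
  if (any(!is.finite(samples)))
    stop("non-finite analytic samples", call. = FALSE)
  structure(list(config = config, samples = samples),
            class = "analytic_ensemble")
}

#' Discrete analytic signal of a real sequence
#'
#' The frequency-domain construction of the discrete analytic signal:
#' forward DFT, multiply bin `k` (0-based) by `h[k]` where `h[0] = 1`,
#' `h[n/2] = 1` for even `n`, `h[k] = 2` for `0 < k < n/2`, `h[k] = 0` for
#' `k > n/2`, then inverse DFT. The real part equals the input to machine
#' precision; the imaginary part is the discrete Hilbert transform. The
#' sequence is processed at native length (no padding) so the
#' sample-to-depth mapping is exact.
#'
#' @param line real numeric vector, length >= 2, all finite.
#' @return complex vector of the same length with a one-sided spectrum.
#' @examples
#' n <- 64; k <- 5
#' a <- analytic_signal(cos(2 * pi * k * (0:(n - 1)) / n))
#' max(Mod(a - exp(2i * pi * k * (0:(n - 1)) / n)))  # ~ 1e-15
#' @export
analytic_signal <- function(line) {
  n <- length(line)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (!all(is.finite(line))) stop("non-finite input", call. = FALSE)
  h <- analytic_multiplier(n)
  stats::fft(stats::fft(line) * h, inverse = TRUE) / n
}

# The one-sided spectrum multiplier h[], 0-based bins as documented above.
analytic_multiplier <- function(n) {
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  h
}

# Design the band-pass FIR: windowed-sinc, Hamming design window, order
# chosen so the transition width is <= 0.1 * f0. Returns the tap vector.
design_bandpass <- function(low, high, fs, f0) {
  if (!(0 < low && low < high && high < fs / 2))
    stop("band [", low, ", ", high, "] Hz must satisfy 0 < low < high < fs/2",
         call. = FALSE)
  # Hamming windowed-sinc transition width ~ 3.3 * fs / n_taps
  n_taps <- 2L * ceiling(3.3 * fs / (0.1 * f0) / 2) + 1L
  signal::fir1(n_taps - 1L, c(low, high) / (fs / 2), type = "pass")
}

# Zero-phase (forward-backward) FIR filtering of every column of a matrix,
# by FFT convolution with the filter autocorrelation g = h * rev(h)
# (symmetric, zero net phase). Edges see implicit zero padding. Works for
# real or complex input.
zero_phase_filter_cols <- function(X, h) {
  n <- nrow(X)
  m <- length(h)
  g <- stats::convolve(h, rev(h), type = "open")  # length 2m - 1, centre m
  nfft <- stats::nextn(n + 2L * m, 2)
  G <- stats::fft(c(g, rep(0, nfft - length(g))))
  P <- rbind(X, matrix(0, nfft - n, ncol(X)))
  Y <- stats::mvfft(stats::mvfft(P) * G, inverse = TRUE) / nfft
  # full convolution index k maps to output sample k - (m - 1); keep 1..n
  out <- Y[m:(m + n - 1L), , drop = FALSE]
  if (is.complex(X)) out else Re(out)
}

#' Band-pass filter an RF ensemble
#'
#' Filters each fast-time echo line with a linear-phase FIR band-pass
#' (windowed-sinc design, Hamming design window, order chosen so the
#' transition width is at most `0.1 * f0`), applied forward-backward for
#' zero net phase so gate depth indices are not shifted by filter delay.
#' The default band is `f0 * (1 -+ fractional_bandwidth)`.
#'
#' @param ensemble an [rf_ensemble()].
#' @param low,high band edges in Hz; both must lie in `(0, fs/2)`.
#' @return an `rf_ensemble` with filtered samples.
#' @export
bandpass_rf <- function(ensemble,
                        low = ensemble$config$f0 * (1 - ensemble$config$fractional_bandwidth),
                        high = ensemble$config$f0 * (1 + ensemble$config$fractional_bandwidth)) {
  stopifnot(inherits(ensemble, "rf_ensemble"))
  cfg <- ensemble$config
  h <- design_bandpass(low, high, cfg$fs, cfg$f0)
  filtered <- t(zero_phase_filter_cols(t(ensemble$samples), h))
  rf_ensemble(cfg, filtered)
}

#' Hilbert-transform quadrature demodulation
#'
#' The digital demodulator: band-pass filtering ([bandpass_rf()]) followed by
#' analytic-signal construction ([analytic_signal()]) along each fast-time
#' line. The complex output carries the echo's envelope and phase; slow-time
#' sampling of its phase at a fixed depth yields the Doppler signal without
#' any analog mixer. The Hilbert transform is applied along fast time (per
#' echo line); gates are extracted afterwards.
#'
#' @param ensemble an [rf_ensemble()].
#' @param band numeric length-2 `(low, high)` in Hz, or `NULL` to skip the
#'   band-pass stage (pre-filtered input).
#' @return an [analytic_ensemble()].
#' @export
demodulate <- function(ensemble,
                       band = ensemble$config$f0 *
                         c(1 - ensemble$config$fractional_bandwidth,
                           1 + ensemble$config$fractional_bandwidth)) {
  stopifnot(inherits(ensemble, "rf_ensemble"))
  if (!is.null(band)) {
    if (length(band) != 2L) stop("band must be (low, high)", call. = FALSE)
    ensemble <- bandpass_rf(ensemble, band[1], band[2])
  }
  X <- t(ensemble$samples)                 # fast time along columns
  n <- nrow(X)
  h <- analytic_multiplier(n)
  A <- stats::mvfft(stats::mvfft(X) * h, inverse = TRUE) / n
  analytic_ensemble(ensemble$config, t(A))
}

#' @export
print.analytic_ensemble <- function(x, ...) {
  cat(sprintf("<analytic_ensemble> %d pulses x %d fast-time samples (complex I/Q)\n",
              nrow(x$samples), ncol(x$samples)))
  invisible(x)
}
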