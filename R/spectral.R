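#' Short-time spectrum parameters
#'
#' Parameters of the sonogram computation: slow-time samples per segment,
#' hop between segment starts, zero-padded FFT length, and the display
#' dynamic range. The analysis window is fixed to the symmetric Hamming
#' window `w[i] = 0.54 - 0.46 cos(2 pi i / (L - 1))`.
#'
#' Defaults: `window_length = 128` pulses, `hop = window_length / 4`,
#' `nfft = 4 * window_length`. Zero padding refines peak localisation to
#' `prf / nfft` without narrowing the (window-limited) mainlobe.
#'
#' @param window_length slow-time samples per segment.
#' @param hop samples between segment starts, `1 <= hop <= window_length`.
#' @param nfft FFT length `>= window_length` (zero-padded).
#' @param dynamic_range display dynamic range in dB, positive.
#' @return object of class `spectrogram_params`.
#' @export
spectrogram_params <- function(window_length = 128L,
                               hop = window_length %/% 4L,
                               nfft = 4L * window_length,
                               dynamic_range = 50) {
  window_length <- as.integer(window_length)
  hop <- as.integer(hop)
  nfft <- as.integer(nfft)
  if (!(1L <= hop && hop <= window_length && window_length <= nfft))
    stop("need 1 <= hop <= window_length <= nfft", call. = FALSE)
  if (dynamic_range <= 0) stop("dynamic_range must be > 0", call. = FALSE)
  structure(list(window_length = window_length, hop = hop, nfft = nfft,
                 window = "hamming", dynamic_range = as.numeric(dynamic_range)),
            class = "spectrogram_params")
}

# Symmetric Hamming window of length L.
hamming_window <- function(L) {
  if (L == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
}

# Zero-centred Doppler frequency axis for an nfft-point CFFT at rate prf.
# For even nfft the single ambiguous -Nyquist bin is dropped so the axis is
# exactly symmetric about 0. Returns list(freq, order) with `order` the
# permutation of 1-based FFT bins.
doppler_axis <- function(nfft, prf) {
  k <- 0:(nfft - 1)
  f <- k / nfft * prf
  f[f >= prf / 2] <- f[f >= prf / 2] - prf
  keep <- !(nfft %% 2 == 0 & k == nfft / 2)
  ord <- order(f[keep])
  list(freq = f[keep][ord], order = which(keep)[ord])
}

#' Sonogram of a gated Doppler signal
#'
#' The spectrum-extraction stage: each slow-time segment is multiplied by
#' the symmetric Hamming window, zero-padded to `nfft`, transformed by a
#' complex FFT, reordered to a zero-centred frequency axis, and reduced to
#' its envelope (complex magnitude). After all segments, the envelope is
#' converted to dB relative to the gate's maximum linear envelope and
#' clipped at `-dynamic_range`. The negative-frequency half represents
#' motion away from the transducer.
#'
#' An all-zero signal has a degenerate reference; the output is then defined
#' as a uniform floor at `-dynamic_range` and a warning is logged.
#'
#' @param signal complex slow-time Doppler signal at rate `prf`; length must
#'   be at least `window_length`.
#' @param params a [spectrogram_params()].
#' @param prf slow-time sampling rate, Hz.
#' @param gate_depth optional gate depth (m), carried as metadata.
#' @return object of class `sonogram`: list with `db` (frequency bins x
#'   segments, values in `[-dynamic_range, 0]`), `freq` (Hz, symmetric about
#'   0, ascending), `time` (segment-centre times, s, pulse 0 at t = 0),
#'   `ref` (linear envelope maximum used as the 0 dB reference — per gate),
#'   `params`, `prf`, `gate_depth`.
#' @export
sonogram <- function(signal, params, prf, gate_depth = NA_real_) {
  stopifnot(inherits(params, "spectrogram_params"))
  L <- params$window_length
  n <- length(signal)
  if (n < L)
    stop("signal (", n, " pulses) shorter than window_length = ", L,
         call. = FALSE)
  w <- hamming_window(L)
  starts <- seq(1L, n - L + 1L, by = params$hop)
  ax <- doppler_axis(params$nfft, prf)
  env <- vapply(starts, function(s) {
    seg <- signal[s:(s + L - 1L)] * w
    Mod(stats::fft(c(seg, rep(0, params$nfft - L))))[ax$order]
  }, numeric(length(ax$freq)))
  env <- matrix(env, nrow = length(ax$freq))
  ref <- max(env)
  if (ref == 0) {
    warning("all-zero gate signal: sonogram set to the uniform floor",
            call. = FALSE)
    db <- matrix(-params$dynamic_range, nrow(env), ncol(env))
  } else {
    db <- pmax(20 * log10(pmax(env / ref, .Machine$double.xmin)),
               -params$dynamic_range)
  }
  structure(list(db = db, freq = ax$freq,
                 time = (starts - 1 + (L - 1) / 2) / prf,
                 ref = ref, params = params, prf = prf,
                 gate_depth = gate_depth),
            class = "sonogram")
}

#' @export
print.sonogram <- function(x, ...) {
  cat(sprintf("<sonogram> %d frequency bins x %d segments, PRF %.3f kHz",
              nrow(x$db), ncol(x$db), x$prf / 1e3))
  if (!is.na(x$gate_depth)) cat(sprintf(", gate at %.2f mm", 1e3 * x$gate_depth))
  cat(sprintf("\n  dynamic range %.0f dB, 0 dB reference %.4g (linear)\n",
              x$params$dynamic_range, x$ref))
  invisible(x)
}

#' Sonograms for every gate of a gate ensemble
#'
#' Applies [sonogram()] to each gate's slow-time signal with shared
#' parameters and a shared time axis. Each gate is normalised to its own
#' maximum envelope (per-gate 0 dB reference), so every gate's trace is
#' uniformly visible regardless of echo strength; the reference is recorded
#' in each sonogram's metadata.
#'
#' @param gates a [gate_ensemble()].
#' @param params a [spectrogram_params()].
#' @return list of `sonogram` objects, one per gate, in gate order.
#' @export
multigate_sonograms <- function(gates, params = spectrogram_params()) {
  stopifnot(inherits(gates, "gate_ensemble"))
  lapply(seq_len(nrow(gates$signals)), function(g)
    sonogram(gates$signals[g, ], params, gates$config$prf,
             gate_depth = gates$depths[g]))
}

#' Render a sonogram as a grey-map image
#'
#' dB values on a grey scale (black = floor, white = 0 dB), time on the
#' horizontal axis, Doppler frequency (zero-centred) on the vertical axis.
#'
#' @param x a [sonogram()].
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.sonogram <- function(x, ...) {
  graphics::image(x$time, x$freq, t(x$db),
                  col = grDevices::gray.colors(256, start = 0, end = 1),
                  xlab = "time (s)", ylab = "Doppler frequency (Hz)",
                  main = if (!is.na(x$gate_depth))
                    sprintf("gate at %.2f mm", 1e3 * x$gate_depth) else "",
                  useRaster = TRUE, ...)
  invisible(x)
}
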