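#' Doppler shift to angle-corrected velocity (and back)
#'
#' The pulsed-wave Doppler equation: a target moving with speed `v` along
#' its motion axis, at angle `theta` to the beam, shifts the slow-time
#' frequency by `f_d = 2 v cos(theta) f0 / c`. The inverse,
#' `v = f_d c / (2 f0 cos(theta))`, is the angle-corrected velocity.
#' Sign convention (package-wide): positive velocity toward the transducer,
#' so flow away from the probe appears at negative `f_d` and negative `v`.
#'
#' @param f_d Doppler shift, Hz (vectorised).
#' @param config an [acquisition_config()]; `doppler_angle` must be far
#'   enough from 90 degrees that `cos(theta) > 1e-6`.
#' @return velocity in m/s (same sign as `f_d`).
#' @examples
#' cfg <- acquisition_config(35e6, 250e6, 3e3, doppler_angle = 75)
#' doppler_to_velocity(-235.3, cfg) * 1e3  # about -20 mm/s
#' @export
doppler_to_velocity <- function(f_d, config) {
  ct <- cos_theta(config)
  if (ct <= 1e-6)
    stop("angle correction undefined: cos(doppler_angle) <= 1e-6",
         call. = FALSE)
  f_d * config$c / (2 * config$f0 * ct)
}

#' @rdname doppler_to_velocity
#' @param v velocity in m/s (positive toward the transducer).
#' @export
velocity_to_doppler <- function(v, config) {
  ct <- cos_theta(config)
  if (ct <= 1e-6)
    stop("angle correction undefined: cos(doppler_angle) <= 1e-6",
         call. = FALSE)
  2 * v * config$f0 * ct / config$c
}

#' Nyquist (maximum unaliased) velocity
#'
#' The aliasing bound of pulsed-wave Doppler: slow-time sampling at the PRF
#' limits unambiguous Doppler shifts to `prf / 2`, hence
#' `v_nyq = prf c / (4 f0 cos(theta))`.
#'
#' @param config an [acquisition_config()].
#' @return speed in m/s.
#' @export
nyquist_velocity <- function(config) {
  doppler_to_velocity(config$prf / 2, config)
}

# -floor_db mainlobe half-width (Hz) of the Hamming analysis window, from a
# finely padded FFT of the window itself.
window_mainlobe_halfwidth <- function(window_length, prf, floor_db,
                                      pad = 8192L) {
  pad <- max(pad, 4L * window_length)
  W <- Mod(stats::fft(c(hamming_window(window_length),
                        rep(0, pad - window_length))))
  thr <- W[1] * 10^(-floor_db / 20)
  half <- W[seq_len(pad %/% 2)]
  i <- which(half < thr)[1]
  if (is.na(i) || i < 2L) return(prf / 2)
  frac <- (half[i - 1] - thr) / (half[i - 1] - half[i])
  (i - 2 + frac) * prf / pad
}

# Relative transit-broadening constant: a scatterer stream crossing the
# pulse's axial resolution cell sigma_z at axial speed v_ax produces a
# Gaussian magnitude spectrum of width sigma_f = v_ax / (2 pi sigma_z)
# = beta * |f_d| with beta = fractional_bandwidth / (2 * 1.17549) — a fixed
# fraction of the Doppler shift, independent of speed.
transit_beta <- function(config) {
  k6 <- sqrt(2 * log(10^(6 / 20)))
  config$fractional_bandwidth / (2 * k6)
}

# Invert the broadening model: the measured -floor_db envelope edge sits at
# |f_edge| = |f_d| + gamma * sqrt((beta f_d)^2 + sigma_w^2), with gamma the
# -floor_db half-width of a unit Gaussian and sigma_w the equivalent
# Gaussian width of the window mainlobe. Solve the quadratic for |f_d|
# (root below |f_edge|); clamp at 0 when the edge is within the window's
# own width of zero.
invert_broadening <- function(f_edge_abs, beta, sigma_w, floor_db) {
  gamma <- sqrt(2 * log(10^(floor_db / 20)))
  gb2 <- (gamma * beta)^2
  a <- f_edge_abs
  disc <- a^2 - (1 - gb2) * (a^2 - (gamma * sigma_w)^2)
  if (disc < 0) return(0)
  f <- (a - sqrt(disc)) / (1 - gb2)
  max(f, 0)
}

#' Estimate the Doppler shift from one sonogram column
#'
#' Reads a single time slot of a sonogram (envelope in dB over the Doppler
#' frequency axis) and returns the Doppler shift, or flags the column as
#' below noise.
#'
#' Modes:
#' * `"peak"` — the frequency of the maximum-magnitude bin (ties broken
#'   toward the lowest `|frequency|`, the conservative velocity). Suited to
#'   narrowband targets (single reflector, wall echoes).
#' * `"max_envelope"` — the envelope-edge reading used for peak-velocity
#'   extraction: the outermost (largest-`|frequency|`) point of the
#'   above-threshold envelope region containing the peak, threshold
#'   `max - floor_db`. With `smooth_bins > 0` the linear envelope is first
#'   smoothed by a centred moving average (speckle on a single STFT column
#'   has ~100% contrast, so the raw bin-wise edge is severely jittered) and
#'   the threshold crossing is linearly interpolated between bins. The edge
#'   overestimates `|f_d|` by the intrinsic spectral broadening — the
#'   window mainlobe, the smoothing width, and the pulse-envelope transit
#'   term (a fixed fraction `beta = bw / 2.351` of `|f_d|` for a moving
#'   scatterer stream). Supplying `broadening` removes all three by a
#'   Gaussian-kernel inversion ([velocity_profile()] builds it from the
#'   acquisition config and window).
#'
#' A column whose (raw) maximum lies within `noise_margin_db` of its median
#' is flagged below-noise (`NA` with attribute): for noise-only columns the
#' STFT magnitude bins are Rayleigh and the max sits ~8.5-10 dB above the
#' median, whatever the absolute level, so the default 14 dB margin
#' separates noise from coherent signal scale-free.
#'
#' @param column envelope in dB over the frequency axis (one sonogram time
#'   slot).
#' @param freq Doppler frequency axis, Hz, matching `column`.
#' @param mode `"max_envelope"` (default) or `"peak"`.
#' @param floor_db envelope-edge threshold below the column maximum, dB.
#' @param noise_margin_db below-noise margin, dB.
#' @param smooth_bins width (bins) of the linear-domain moving average
#'   applied before edge detection; 0 disables (raw bin-wise reading).
#' @param broadening `NULL` (raw edge), or `list(beta =, sigma_w =)`
#'   enabling the broadening correction.
#' @return the Doppler shift in Hz, or `NA` with attribute
#'   `below_noise = TRUE`.
#' @export
estimate_doppler <- function(column, freq, mode = c("max_envelope", "peak"),
                             floor_db = 12, noise_margin_db = 14,
                             smooth_bins = 0L, broadening = NULL) {
  mode <- match.arg(mode)
  if (!length(column)) stop("empty sonogram column", call. = FALSE)
  if (length(column) != length(freq))
    stop("column does not match the frequency axis", call. = FALSE)
  mx <- max(column)
  if (mx - stats::median(column) < noise_margin_db)
    return(structure(NA_real_, below_noise = TRUE))
  peaks <- which(column == mx)
  ipk <- peaks[which.min(abs(freq[peaks]))]     # tie: lowest |frequency|
  if (mode == "peak") return(freq[ipk])

  env <- 10^(column / 20)
  if (smooth_bins > 1L) {
    env <- as.numeric(stats::filter(env, rep(1 / smooth_bins, smooth_bins),
                                    sides = 2))
    env[is.na(env)] <- 0
  }
  thr <- max(env) * 10^(-floor_db / 20)
  ipk <- which.max(env)
  above <- env >= thr
  lo <- ipk; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- ipk; while (hi < length(env) && above[hi + 1L]) hi <- hi + 1L
  # outer boundary of the run on the larger-|frequency| side (the peak's
  # sign decides ties); with smoothing active the crossing is linearly
  # interpolated between the last above- and first below-threshold bins,
  # otherwise the raw edge bin is reported
  outer_hi <- if (abs(freq[hi]) != abs(freq[lo])) abs(freq[hi]) > abs(freq[lo])
              else freq[ipk] >= 0
  f_edge <- if (outer_hi) {
    if (smooth_bins > 1L && hi < length(env)) {
      frac <- (env[hi] - thr) / (env[hi] - env[hi + 1L])
      freq[hi] + frac * (freq[hi + 1L] - freq[hi])
    } else freq[hi]
  } else {
    if (smooth_bins > 1L && lo > 1L) {
      frac <- (env[lo] - thr) / (env[lo] - env[lo - 1L])
      freq[lo] + frac * (freq[lo - 1L] - freq[lo])
    } else freq[lo]
  }
  if (is.null(broadening)) return(f_edge)
  sign(f_edge) * invert_broadening(abs(f_edge), broadening$beta,
                                   broadening$sigma_w, floor_db)
}

#' Depth x time velocity profile from multigate sonograms
#'
#' Applies [estimate_doppler()] to every gate and time slot, converts the
#' shifts through [doppler_to_velocity()], and assembles the signed velocity
#' matrix (positive toward the transducer) with its below-noise mask.
#'
#' @param sonograms list of [sonogram()] objects sharing time and frequency
#'   axes (as produced by [multigate_sonograms()]).
#' @param config the [acquisition_config()] of the acquisition.
#' @param mode,floor_db,noise_margin_db passed to [estimate_doppler()].
#' @param correct_broadening apply the intrinsic spectral-broadening
#'   correction in `max_envelope` mode (default `TRUE`).
#' @return object of class `velocity_profile`: `depths` (m), `times` (s),
#'   `velocity` (m/s, gates x times, `NA` where masked), `mask` (logical,
#'   `TRUE` = below noise), `mode`, `config`.
#' @export
velocity_profile <- function(sonograms, config,
                             mode = c("max_envelope", "peak"),
                             floor_db = 12, noise_margin_db = 14,
                             correct_broadening = TRUE) {
  mode <- match.arg(mode)
  if (!length(sonograms)) stop("no sonograms", call. = FALSE)
  t0 <- sonograms[[1]]$time
  f0ax <- sonograms[[1]]$freq
  for (s in sonograms)
    if (!isTRUE(all.equal(s$time, t0)) || !isTRUE(all.equal(s$freq, f0ax)))
      stop("sonograms do not share time/frequency axes", call. = FALSE)
  p <- sonograms[[1]]$params
  # smoothing width: one Hamming mainlobe (4 bins of prf / window_length)
  smooth_bins <- max(1L, round(4 * p$nfft / p$window_length))
  broadening <- NULL
  if (mode == "max_envelope" && correct_broadening) {
    hw <- window_mainlobe_halfwidth(p$window_length, config$prf, floor_db)
    gamma <- sqrt(2 * log(10^(floor_db / 20)))
    sigma_rect <- (smooth_bins * config$prf / p$nfft) / sqrt(12)
    broadening <- list(beta = transit_beta(config),
                       sigma_w = sqrt((hw / gamma)^2 + sigma_rect^2))
  }
  ng <- length(sonograms); nt <- length(t0)
  vel <- matrix(NA_real_, ng, nt)
  mask <- matrix(FALSE, ng, nt)
  for (g in seq_len(ng)) {
    son <- sonograms[[g]]
    for (j in seq_len(nt)) {
      fd <- estimate_doppler(son$db[, j], son$freq, mode = mode,
                             floor_db = floor_db,
                             noise_margin_db = noise_margin_db,
                             smooth_bins = if (mode == "max_envelope")
                               smooth_bins else 0L,
                             broadening = broadening)
      if (is.na(fd)) mask[g, j] <- TRUE
      else vel[g, j] <- doppler_to_velocity(fd, config)
    }
  }
  structure(list(
    depths = vapply(sonograms, function(s) s$gate_depth, numeric(1)),
    times = t0, velocity = vel, mask = mask, mode = mode, config = config
  ), class = "velocity_profile")
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf("<velocity_profile> %d gates x %d time slots (%s estimator)\n",
              nrow(x$velocity), ncol(x$velocity), x$mode))
  cat(sprintf("  unmasked: %.0f%%; median unmasked speed %.2f mm/s\n",
              100 * mean(!x$mask),
              1e3 * stats::median(abs(x$velocity[!x$mask]))))
  invisible(x)
}

#' Contiguous unmasked depth extent of a velocity profile
#'
#' A gate counts as detected when at least `min_frac` of its time slots are
#' unmasked; the extent is the longest contiguous run of detected gates
#' times the gate spacing — the measured lumen width of a multigate flow
#' acquisition.
#'
#' @param profile a [velocity_profile()] with evenly spaced gates.
#' @param min_frac minimum unmasked fraction for a gate to count.
#' @return list with `span` (m), `n_gates`, `spacing` (m), `gates` (logical
#'   per-gate detection vector).
#' @export
contiguous_unmasked_span <- function(profile, min_frac = 0.5) {
  det <- rowMeans(!profile$mask) >= min_frac
  spacing <- if (length(profile$depths) > 1)
    stats::median(diff(profile$depths)) else NA_real_
  r <- rle(det)
  n <- if (any(r$values)) max(r$lengths[r$values]) else 0L
  list(span = n * spacing, n_gates = n, spacing = spacing, gates = det)
}

#' Integrate a velocity trace to displacement
#'
#' Cumulative trapezoidal integration with `d(t[1]) = 0`:
#' `d(t_k) = sum_i (v_i + v_(i+1)) / 2 * (t_(i+1) - t_i)`. Used to turn
#' wall-velocity traces into wall displacement.
#'
#' @param times strictly increasing times, s, length >= 2.
#' @param velocity velocities at `times`, m/s; no `NA` gaps (interpolate or
#'   split first, e.g. with [stats::approx()]).
#' @return object of class `displacement_trace`: `times`, `displacement`
#'   (m, starting at 0).
#' @export
integrate_displacement <- function(times, velocity) {
  if (length(times) < 2L) stop("need at least 2 time points", call. = FALSE)
  if (length(times) != length(velocity))
    stop("times and velocity lengths differ", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(velocity)))
    stop("velocity trace contains non-finite values; fill masked gaps first",
         call. = FALSE)
  n <- length(times)
  d <- c(0, cumsum((velocity[-1] + velocity[-n]) / 2 * diff(times)))
  structure(list(times = times, displacement = d),
            class = "displacement_trace")
}

#' Wall displacement trace for one gate of a velocity profile
#'
#' Extracts a single gate's velocity trace, linearly interpolates interior
#' masked slots (constant extrapolation at the ends), and integrates to
#' displacement.
#'
#' @param profile a [velocity_profile()].
#' @param gate gate index (row of the profile).
#' @return a `displacement_trace`.
#' @export
gate_displacement <- function(profile, gate) {
  v <- profile$velocity[gate, ]
  if (all(is.na(v)))
    stop("gate ", gate, " is entirely below noise", call. = FALSE)
  if (anyNA(v))
    v <- stats::approx(profile$times[!is.na(v)], v[!is.na(v)],
                       xout = profile$times, rule = 2)$y
  integrate_displacement(profile$times, v)
}
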