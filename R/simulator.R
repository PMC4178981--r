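#' Transmit pulse specification
#'
#' A sinusoidal burst at the carrier frequency, `tx_cycles` cycles long,
#' shaped by a Gaussian envelope whose -6 dB spectral full width equals
#' `fractional_bandwidth * f0`. The two-way transducer response is folded
#' into this single envelope; amplitudes are arbitrary linear units.
#'
#' @param f0 carrier frequency, Hz.
#' @param tx_cycles integer >= 1, burst length in carrier cycles.
#' @param fractional_bandwidth -6 dB fractional bandwidth, in (0, 2).
#' @return object of class `pulse_spec`.
#' @export
pulse_spec <- function(f0, tx_cycles, fractional_bandwidth) {
  if (tx_cycles < 1) stop("tx_cycles must be >= 1", call. = FALSE)
  if (fractional_bandwidth <= 0 || fractional_bandwidth >= 2)
    stop("fractional_bandwidth must lie in (0, 2)", call. = FALSE)
  structure(list(f0 = as.numeric(f0), tx_cycles = as.integer(tx_cycles),
                 fractional_bandwidth = as.numeric(fractional_bandwidth)),
            class = "pulse_spec")
}

as_pulse_spec <- function(x) {
  if (inherits(x, "pulse_spec")) return(x)
  if (inherits(x, "acquisition_config"))
    return(pulse_spec(x$f0, x$tx_cycles, x$fractional_bandwidth))
  stop("cannot interpret object as a pulse spec", call. = FALSE)
}

# Continuous-time pulse, zero-centred, peak amplitude 1 at t = 0, zero
# outside |t| > duration/2. Vectorised over t (seconds).
pulse_eval <- function(t, spec) {
  dur <- spec$tx_cycles / spec$f0
  sigma <- pulse_sigma_t(spec$f0, spec$fractional_bandwidth)
  out <- cos(2 * pi * spec$f0 * t) * exp(-t^2 / (2 * sigma^2))
  out[abs(t) > dur / 2] <- 0
  out
}

#' Synthesise the transmit pulse waveform
#'
#' Samples the Gaussian-enveloped sinusoid at rate `fs`: a burst lasting
#' `tx_cycles / f0` seconds, zero-centred in time, normalised to peak
#' amplitude exactly 1. The number of samples is `round(fs * tx_cycles / f0)`.
#'
#' @param spec a [pulse_spec()] (or an [acquisition_config()], whose pulse
#'   fields are used).
#' @param fs sampling rate, Hz; must exceed `2 * f0`.
#' @return numeric vector of pulse samples.
#' @examples
#' p <- synth_pulse(pulse_spec(35e6, 7, 0.55), 250e6)
#' length(p)  # 50
#' @export
synth_pulse <- function(spec, fs) {
  spec <- as_pulse_spec(spec)
  if (fs <= 2 * spec$f0)
    stop("fs = ", fs, " aliases the carrier: need fs > 2 * f0 = ",
         2 * spec$f0, call. = FALSE)
  n <- round(fs * spec$tx_cycles / spec$f0)
  t <- (seq_len(n) - (n + 1) / 2) / fs
  p <- pulse_eval(t, spec)
  p / max(abs(p))
}

#' Motion models for the RF simulator
#'
#' Three variants of scatterer motion, mirroring the validation experiments
#' the simulator emulates:
#'
#' * `motion_translation(speed, depth)` — a reflector translating at constant
#'   speed along the motion axis. `speed > 0` moves *away* from the
#'   transducer (depth increasing), the negative-velocity convention of the
#'   processing chain; start depth in metres.
#' * `motion_parabolic_flow(centre_depth, diameter, v_max, wrap_window)` —
#'   laminar (Poiseuille) pipe flow, axial speed `v(r) = v_max (1 - (r/R)^2)`
#'   with `R = diameter / 2`; positive `v_max` flows away from the
#'   transducer. Scatterer radial coordinate is mapped to depth offset from
#'   the vessel centre along the beam line (lateral beam geometry is not
#'   modelled). Each scatterer advances at its own `v(r)` and is refreshed
#'   periodically within a `wrap_window` (default 0.3 mm) around its home
#'   depth, with reflectivity redrawn per cycle: this emulates finite beam
#'   transit while preserving the depth-velocity correlation and slow-time
#'   stationarity.
#' * `motion_sinusoidal_wall(anterior_depth, posterior_depth, amplitude,
#'   frequency)` — two specular interfaces oscillating in antiphase (lumen
#'   pulsation): anterior displacement `-A sin(2 pi f t)` (toward the
#'   transducer first), posterior `+A sin(2 pi f t)`. `posterior_depth = NA`
#'   simulates a single interface.
#'
#' @param speed m/s along the motion axis (positive = away).
#' @param depth start depth of the translating reflector, m.
#' @param centre_depth vessel centre depth, m.
#' @param diameter vessel lumen diameter, m (> 0).
#' @param v_max peak axial speed, m/s (positive = away).
#' @param wrap_window scatterer refresh window, m.
#' @param anterior_depth,posterior_depth interface rest depths, m.
#' @param amplitude wall displacement amplitude, m (documented assumption:
#'   much smaller than the gate spacing in use).
#' @param frequency wall oscillation frequency, Hz (must be `< prf / 2` of
#'   the config used for simulation).
#' @return object of class `motion_model`.
#' @name motion_model
NULL

#' @rdname motion_model
#' @export
motion_translation <- function(speed, depth) {
  structure(list(variant = "constant_translation",
                 speed = as.numeric(speed), depth = as.numeric(depth)),
            class = "motion_model")
}

#' @rdname motion_model
#' @export
motion_parabolic_flow <- function(centre_depth, diameter, v_max,
                                  wrap_window = 0.3e-3) {
  if (diameter <= 0) stop("diameter must be > 0", call. = FALSE)
  structure(list(variant = "parabolic_flow",
                 centre_depth = as.numeric(centre_depth),
                 diameter = as.numeric(diameter),
                 v_max = as.numeric(v_max),
                 wrap_window = as.numeric(wrap_window)),
            class = "motion_model")
}

#' @rdname motion_model
#' @export
motion_sinusoidal_wall <- function(anterior_depth, posterior_depth = NA,
                                   amplitude, frequency) {
  structure(list(variant = "sinusoidal_wall",
                 anterior_depth = as.numeric(anterior_depth),
                 posterior_depth = as.numeric(posterior_depth),
                 amplitude = as.numeric(amplitude),
                 frequency = as.numeric(frequency)),
            class = "motion_model")
}

#' True axial-corrected speed of a motion model at a given depth
#'
#' Ground truth for test harnesses: the signed velocity (positive toward the
#' transducer, the package-wide convention) that an ideal estimator should
#' report at `depth`, before any Doppler processing. For `parabolic_flow`
#' this is `-v_max (1 - (r/R)^2)` with `r` the depth offset from the vessel
#' centre (`NA` outside the lumen); for `constant_translation` it is
#' `-speed` everywhere; for `sinusoidal_wall` it is the peak wall speed
#' `2 pi f A` (magnitude) at the interfaces, `NA` elsewhere.
#'
#' @param motion a `motion_model`.
#' @param depth depth(s), m.
#' @return velocity in m/s (vectorised over `depth`).
#' @export
true_velocity <- function(motion, depth) {
  switch(motion$variant,
    constant_translation = rep(-motion$speed, length(depth)),
    parabolic_flow = {
      r <- depth - motion$centre_depth
      R <- motion$diameter / 2
      v <- -motion$v_max * (1 - (r / R)^2)
      v[abs(r) > R] <- NA_real_
      v
    },
    sinusoidal_wall = {
      v <- rep(NA_real_, length(depth))
      peak <- 2 * pi * motion$frequency * motion$amplitude
      v[abs(depth - motion$anterior_depth) < 1e-9] <- peak
      if (!is.na(motion$posterior_depth))
        v[abs(depth - motion$posterior_depth) < 1e-9] <- peak
      v
    },
    stop("unknown motion variant", call. = FALSE)
  )
}

#' Construct a scatterer field for a motion model
#'
#' Places scatterers along the beam line, deterministic given `seed`:
#'
#' * `constant_translation` — one strong reflector (amplitude 1) at the
#'   motion model's start depth.
#' * `parabolic_flow` — `round(density * diameter_mm)` scatterers uniformly
#'   filling the lumen's depth span, each tagged with its radial coordinate
#'   `r = depth - centre_depth`; reflectivities drawn from a standard normal.
#' * `sinusoidal_wall` — strong reflectors (amplitude 1) at the anterior and
#'   (if given) posterior interface depths.
#'
#' @param motion a `motion_model`.
#' @param config an [acquisition_config()]; the field must fit inside its
#'   depth range.
#' @param density scatterers per millimetre of lumen (flow variant), > 0.
#' @param seed integer RNG seed.
#' @return object of class `scatterer_field`: data frame with columns
#'   `depth` (m), `r` (m, `NA` unless flow), `amplitude`.
#' @export
make_field <- function(motion, config, density = 30, seed = 1L) {
  validate_config(config)
  if (density <= 0) stop("density must be > 0", call. = FALSE)
  dmax <- max_depth(config)
  fld <- switch(motion$variant,
    constant_translation = data.frame(depth = motion$depth, r = NA_real_,
                                      amplitude = 1),
    parabolic_flow = {
      R <- motion$diameter / 2
      if (motion$centre_depth - R < 0 || motion$centre_depth + R >= dmax)
        stop("vessel [", 1e3 * (motion$centre_depth - R), ", ",
             1e3 * (motion$centre_depth + R), "] mm extends beyond the depth",
             " range [0, ", 1e3 * dmax, ") mm", call. = FALSE)
      n <- round(density * motion$diameter * 1e3)
      withr_seed(seed, {
        depth <- motion$centre_depth + stats::runif(n, -R, R)
        data.frame(depth = depth, r = depth - motion$centre_depth,
                   amplitude = stats::rnorm(n))
      })
    },
    sinusoidal_wall = {
      depths <- c(motion$anterior_depth,
                  if (!is.na(motion$posterior_depth)) motion$posterior_depth)
      data.frame(depth = depths, r = NA_real_, amplitude = 1)
    },
    stop("unknown motion variant", call. = FALSE)
  )
  if (any(fld$depth < 0 | fld$depth >= dmax))
    stop("scatterer depth outside [0, ", 1e3 * dmax, ") mm", call. = FALSE)
  class(fld) <- c("scatterer_field", "data.frame")
  fld
}

# Run code with a local RNG seed without disturbing the caller's RNG state.
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Simulate an RF echo ensemble
#'
#' Generates the `n_slow x n_fast` real RF matrix for a scatterer field under
#' a motion model. For pulse index `n` (slow time) each scatterer `k` is
#' advanced along its trajectory (see [motion_model]); echo line `n` is
#' `sum_k amplitude_k * p(t - 2 * depth_k(n) / c)` sampled at `fs`, where `p`
#' is the Gaussian-enveloped transmit pulse, evaluated at exact (sub-sample)
#' delays. White Gaussian noise is added at `noise_db` decibels relative to
#' the RMS of the noiseless ensemble (all samples); `-Inf` disables noise.
#'
#' Motion projects onto the beam axis through `cos(doppler_angle)`; motion
#' away from the transducer increases depth and appears as *negative*
#' velocity downstream. If any scatterer's axial Doppler shift
#' `|2 v_axial f0 / c|` reaches `prf / 2` a warning is raised (aliasing is
#' physical, not fatal).
#'
#' @param field a [make_field()] result.
#' @param motion the `motion_model` the field was built for.
#' @param config an [acquisition_config()].
#' @param noise_db noise level in dB relative to signal RMS (`-Inf` = none).
#' @param seed integer RNG seed for the noise (and flow reflectivity
#'   refresh), independent of the field seed.
#' @return an [rf_ensemble()].
#' @export
simulate_ensemble <- function(field, motion, config, noise_db = -30,
                              seed = 1L) {
  validate_config(config)
  spec <- as_pulse_spec(config)
  dur <- spec$tx_cycles / spec$f0
  if (dur * config$fs > config$n_fast)
    stop("pulse (", round(dur * config$fs), " samples) does not fit within ",
         "n_fast = ", config$n_fast, call. = FALSE)
  n_slow <- config$n_slow
  n_fast <- config$n_fast
  ct <- cos_theta(config)
  tn <- (seq_len(n_slow) - 1) / config$prf  # pulse firing times, s

  # per-scatterer depth trajectories: list of (n_slow vector, amplitude
  # vector over slow time)
  trajectories <- switch(motion$variant,
    constant_translation = lapply(seq_len(nrow(field)), function(k) {
      list(depth = field$depth[k] + motion$speed * ct * tn,
           amp = rep(field$amplitude[k], n_slow))
    }),
    sinusoidal_wall = {
      if (2 * motion$frequency >= config$prf)
        stop("wall oscillation frequency must be < prf / 2", call. = FALSE)
      lapply(seq_len(nrow(field)), function(k) {
        # anterior (first row) contracts first (moves toward transducer),
        # posterior moves away: antiphase lumen pulsation
        sgn <- if (k == 1L) -1 else 1
        list(depth = field$depth[k] +
               sgn * motion$amplitude * sin(2 * pi * motion$frequency * tn) * ct,
             amp = rep(field$amplitude[k], n_slow))
      })
    },
    parabolic_flow = {
      R <- motion$diameter / 2
      lam <- motion$wrap_window
      withr_seed(seed + 1L, lapply(seq_len(nrow(field)), function(k) {
        v_ax <- motion$v_max * (1 - (field$r[k] / R)^2) * ct
        travel <- v_ax * tn
        cycle <- floor((travel + lam / 2) / lam)
        depth <- field$depth[k] + (travel + lam / 2) %% lam - lam / 2
        ncyc <- max(cycle) - min(cycle) + 1L
        amps <- c(field$amplitude[k],
                  if (ncyc > 1L) stats::rnorm(ncyc - 1L))
        list(depth = depth, amp = amps[cycle - min(cycle) + 1L],
             v_ax = abs(v_ax))
      }))
    },
    stop("unknown motion variant", call. = FALSE)
  )

  # aliasing check on the extreme axial speed actually realised (for the
  # flow variant the wrap jumps are not motion, so the analytic v_ax is used)
  v_ax_max <- max(vapply(trajectories, function(tr) {
    if (!is.null(tr$v_ax)) return(tr$v_ax)
    if (n_slow < 2L) return(0)
    max(abs(diff(tr$depth))) * config$prf
  }, numeric(1)))
  if (2 * v_ax_max * config$f0 / config$c >= config$prf / 2)
    warning("axial Doppler shift ", round(2 * v_ax_max * config$f0 / config$c),
            " Hz reaches the slow-time Nyquist limit prf/2 = ",
            config$prf / 2, " Hz: expect aliasing", call. = FALSE)

  E <- matrix(0, n_slow, n_fast)
  n_sup <- ceiling(dur * config$fs) + 2L  # samples spanning the pulse support
  offs <- 0:(n_sup - 1L)
  for (tr in trajectories) {
    tau <- 2 * tr$depth / config$c
    i0 <- floor((tau - dur / 2) * config$fs)          # 0-based first index
    tmat <- outer(i0, offs, "+") / config$fs - tau    # n_slow x n_sup times
    vals <- pulse_eval(tmat, spec) * tr$amp
    cols <- outer(i0, offs, "+") + 1L                 # 1-based columns
    ok <- cols >= 1L & cols <= n_fast & vals != 0
    idx <- (cols[ok] - 1L) * n_slow + row(cols)[ok]   # linear indices
    E[idx] <- E[idx] + vals[ok]
  }

  if (is.finite(noise_db)) {
    sig_rms <- sqrt(mean(E^2))
    if (sig_rms == 0) sig_rms <- 1
    withr_seed(seed, {
      E <- E + matrix(stats::rnorm(n_slow * n_fast,
                                   sd = sig_rms * 10^(noise_db / 20)),
                      n_slow, n_fast)
    })
  }
  rf_ensemble(config, E)
}
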