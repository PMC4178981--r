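#' Pipeline stage parameters
#'
#' Flat key-value document controlling [run_pipeline()]. Unknown keys are an
#' error (this catches silent typos). Keys and defaults:
#'
#' | key | default | meaning |
#' |---|---|---|
#' | `bandpass` | `TRUE` | apply the band-pass stage |
#' | `band_low_hz`, `band_high_hz` | `f0 (1 -+ bw)` | band edges |
#' | `gates_mm` | — | explicit gate centre depths, mm |
#' | `gate_span_mm` | — | `[start, stop, spacing]` in mm (alternative) |
#' | `gate_length` | `1` | odd samples per gate |
#' | `clutter_mode` | `"off"` | `"off"` or `"highpass"` |
#' | `clutter_cutoff_hz` | `0.02 * prf` | high-pass cutoff |
#' | `window_length` | `128` | STFT window, pulses |
#' | `hop` | `window_length / 4` | STFT hop, pulses |
#' | `nfft` | `4 * window_length` | zero-padded CFFT length |
#' | `dynamic_range_db` | `50` | sonogram dynamic range |
#' | `estimator` | `"max_envelope"` | or `"peak"` |
#' | `floor_db` | `12` | envelope-edge threshold |
#' | `noise_margin_db` | `14` | below-noise mask margin |
#' | `correct_broadening` | `TRUE` | spectral-broadening correction |
#'
#' @param params named list (e.g. parsed from a JSON config file).
#' @param config the [acquisition_config()] the defaults derive from.
#' @return completed parameter list.
#' @export
pipeline_params <- function(params, config) {
  defaults <- list(
    bandpass = TRUE,
    band_low_hz = config$f0 * (1 - config$fractional_bandwidth),
    band_high_hz = config$f0 * (1 + config$fractional_bandwidth),
    gates_mm = NULL, gate_span_mm = NULL, gate_length = 1L,
    clutter_mode = "off", clutter_cutoff_hz = 0.02 * config$prf,
    window_length = 128L, hop = NULL, nfft = NULL,
    dynamic_range_db = 50, estimator = "max_envelope",
    floor_db = 12, noise_margin_db = 14, correct_broadening = TRUE
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown pipeline parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- utils::modifyList(defaults, params)
  out$window_length <- as.integer(out$window_length)
  if (is.null(out$hop)) out$hop <- out$window_length %/% 4L
  if (is.null(out$nfft)) out$nfft <- 4L * out$window_length
  out$hop <- as.integer(out$hop)
  out$nfft <- as.integer(out$nfft)
  out$gate_length <- as.integer(out$gate_length)
  if (is.null(out$gates_mm) && is.null(out$gate_span_mm))
    stop("pipeline parameters must define gates_mm or gate_span_mm",
         call. = FALSE)
  out
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
}

log_stage <- function(name, ...) {
  message(sprintf("pwdoppler | %-10s | %s", name, paste0(...)))
}

#' Run the full multigate PW Doppler pipeline
#'
#' Chains the processing stages in acquisition order: band-pass filtering,
#' Hilbert-transform analytic-signal demodulation, multigate slow-time
#' extraction, optional clutter filtering, Hamming/CFFT sonogram generation
#' per gate, and spectral velocity estimation with angle correction. Every
#' stage is logged to stderr with its parameters; results are returned (and
#' optionally written) only to declared outputs. A stage failure propagates
#' with the stage name attached.
#'
#' @param ensemble an [rf_ensemble()].
#' @param params named list as accepted by [pipeline_params()].
#' @param out_dir optional directory: writes one sonogram container per gate
#'   (`sonogram_gate<k>.bin`) and the result table (`result_table.csv`).
#' @return list with `profile` (a [velocity_profile()]), `sonograms`,
#'   `gates` (the [gate_ensemble()]), and `result_table` (data frame with
#'   columns `gate`, `depth_mm`, `time_s`, `velocity_mm_s`, `masked`).
#' @export
run_pipeline <- function(ensemble, params, out_dir = NULL) {
  stopifnot(inherits(ensemble, "rf_ensemble"))
  cfg <- ensemble$config
  p <- pipeline_params(params, cfg)

  analytic <- if (p$bandpass) {
    log_stage("bandpass", sprintf("band = [%.2f, %.2f] MHz, zero-phase FIR",
                                  p$band_low_hz / 1e6, p$band_high_hz / 1e6))
    stage("demodulate", demodulate(ensemble, c(p$band_low_hz, p$band_high_hz)))
  } else {
    log_stage("bandpass", "skipped (pre-filtered input)")
    stage("demodulate", demodulate(ensemble, band = NULL))
  }
  log_stage("demodulate", "analytic signal per fast-time line (Hilbert/FFT)")

  spec <- stage("gates", {
    if (!is.null(p$gates_mm))
      gate_spec(depths = sort(p$gates_mm) * 1e-3, gate_length = p$gate_length)
    else
      gate_span(p$gate_span_mm[1] * 1e-3, p$gate_span_mm[2] * 1e-3,
                p$gate_span_mm[3] * 1e-3, gate_length = p$gate_length)
  })
  gates <- stage("gates", extract_gates(analytic, spec))
  log_stage("gates", sprintf("%d gates, gate_length = %d",
                             nrow(gates$signals), spec$gate_length))

  if (p$clutter_mode != "off") {
    gates <- stage("clutter",
                   clutter_filter(gates, p$clutter_cutoff_hz, p$clutter_mode))
    log_stage("clutter", sprintf("highpass, cutoff = %.1f Hz",
                                 p$clutter_cutoff_hz))
  } else log_stage("clutter", "off")

  sp <- spectrogram_params(p$window_length, p$hop, p$nfft, p$dynamic_range_db)
  sons <- stage("sonogram", multigate_sonograms(gates, sp))
  log_stage("sonogram", sprintf(
    "window = %d, hop = %d, nfft = %d, dynamic range = %.0f dB",
    sp$window_length, sp$hop, sp$nfft, sp$dynamic_range))

  profile <- stage("velocity", velocity_profile(
    sons, cfg, mode = p$estimator, floor_db = p$floor_db,
    noise_margin_db = p$noise_margin_db,
    correct_broadening = p$correct_broadening))
  log_stage("velocity", sprintf(
    "%s estimator, floor = %.0f dB, noise margin = %.0f dB, %.0f%% unmasked",
    p$estimator, p$floor_db, p$noise_margin_db, 100 * mean(!profile$mask)))

  rt <- result_table(profile)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (g in seq_along(sons))
      write_sonogram(sons[[g]],
                     file.path(out_dir, sprintf("sonogram_gate%03d.bin", g)))
    write_result_table(rt, file.path(out_dir, "result_table.csv"))
    log_stage("write", sprintf("%d sonograms + result table -> %s",
                               length(sons), out_dir))
  }
  list(profile = profile, sonograms = sons, gates = gates, result_table = rt)
}

#' Result table of a velocity profile
#'
#' Long-format record of the profile, one row per gate and time slot, with
#' units recorded in the column names.
#'
#' @param profile a [velocity_profile()].
#' @return data frame with columns `gate`, `depth_mm`, `time_s`,
#'   `velocity_mm_s` (`NA` where masked), `masked`.
#' @export
result_table <- function(profile) {
  ng <- nrow(profile$velocity); nt <- ncol(profile$velocity)
  data.frame(
    gate = rep(seq_len(ng), each = nt),
    depth_mm = rep(1e3 * profile$depths, each = nt),
    time_s = rep(profile$times, ng),
    velocity_mm_s = as.vector(t(profile$velocity)) * 1e3,
    masked = as.vector(t(profile$mask))
  )
}

#' @rdname result_table
#' @param rt a result table.
#' @param path output CSV path.
#' @export
write_result_table <- function(rt, path) {
  utils::write.csv(rt, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a sonogram in the matrix container format
#'
#' The dB matrix with its frequency and time axes and display metadata, in
#' the two-part binary matrix container.
#'
#' @param son a [sonogram()].
#' @param path output path.
#' @export
write_sonogram <- function(son, path) {
  write_matrix_container(
    son$db, path,
    axes = list(freq_hz = son$freq, time_s = son$time),
    meta = list(kind = "sonogram-db", prf = son$prf, ref = son$ref,
                dynamic_range_db = son$params$dynamic_range,
                window_length = son$params$window_length,
                hop = son$params$hop, nfft = son$params$nfft,
                gate_depth_m = if (is.na(son$gate_depth)) NULL
                               else son$gate_depth)
  )
}

#' @rdname write_sonogram
#' @export
read_sonogram <- function(path) {
  ct <- read_matrix_container(path)
  m <- ct$meta
  structure(list(
    db = ct$matrix, freq = ct$axes$freq_hz, time = ct$axes$time_s,
    ref = m$ref,
    params = spectrogram_params(m$window_length, m$hop, m$nfft,
                                m$dynamic_range_db),
    prf = m$prf,
    gate_depth = if (is.null(m$gate_depth_m)) NA_real_ else m$gate_depth_m
  ), class = "sonogram")
}
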