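#' RF ensemble: fast-time x slow-time real sample matrix
#'
#' The raw input of the processing chain: `n_slow` echo lines (one per
#' transmitted pulse) of `n_fast` real samples each, stored as an
#' `n_slow x n_fast` matrix (rows = slow time / pulse index, columns = fast
#' time / depth sample), in arbitrary linear amplitude units, plus the
#' acquisition configuration that produced it.
#'
#' @param config an [acquisition_config()] whose `n_slow`/`n_fast` match.
#' @param samples real matrix, `n_slow` rows x `n_fast` columns, all finite.
#' @return object of class `rf_ensemble`.
#' @export
rf_ensemble <- function(config, samples) {
  validate_config(config)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("samples must be a numeric matrix", call. = FALSE)
  if (nrow(samples) != config$n_slow || ncol(samples) != config$n_fast)
    stop("samples shape (", nrow(samples), " x ", ncol(samples),
         ") does not match config (", config$n_slow, " x ", config$n_fast, ")",
         call. = FALSE)
  bad <- which(!is.finite(samples))
  if (length(bad))
    stop("non-finite sample at [pulse ", row(samples)[bad[1]],
         ", sample ", col(samples)[bad[1]], "]", call. = FALSE)
  structure(list(config = config, samples = samples), class = "rf_ensemble")
}

#' @export
print.rf_ensemble <- function(x, ...) {
  cat(sprintf("<rf_ensemble> %d pulses x %d fast-time samples, RMS %.4g\n",
              nrow(x$samples), ncol(x$samples), sqrt(mean(x$samples^2))))
  print(x$config)
  invisible(x)
}

RF_FORMAT <- "pwdoppler-rf"
MATRIX_FORMAT <- "pwdoppler-matrix"
CONTAINER_VERSION <- "1"

config_to_list <- function(cfg) {
  lst <- unclass(cfg)
  if (is.na(lst$seed)) lst$seed <- NULL   # JSON has no NA
  lst
}

config_from_list <- function(lst) {
  need <- c("f0", "fs", "prf", "c", "doppler_angle", "tx_cycles",
            "fractional_bandwidth", "n_fast", "n_slow")
  miss <- setdiff(need, names(lst))
  if (length(miss))
    stop("container header is missing config fields: ",
         paste(miss, collapse = ", "), call. = FALSE)
  acquisition_config(
    f0 = lst$f0, fs = lst$fs, prf = lst$prf, c = lst$c,
    doppler_angle = lst$doppler_angle, tx_cycles = lst$tx_cycles,
    fractional_bandwidth = lst$fractional_bandwidth,
    n_fast = lst$n_fast, n_slow = lst$n_slow,
    seed = if (is.null(lst$seed) || is.na(lst$seed)) NA_integer_ else lst$seed
  )
}

# Write a two-part container: one line of UTF-8 JSON, then a little-endian
# float32 payload, row-major in the sense of the stated shape.
write_container <- function(path, header, payload) {
  con <- try(file(path, "wb"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop("cannot open '", path, "' for writing", call. = FALSE)
  on.exit(close(con))
  hdr <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA, null = "null")
  writeBin(charToRaw(paste0(as.character(hdr), "\n")), con)
  writeBin(as.numeric(payload), con, size = 4L, endian = "little")
  invisible(path)
}

# Read back header (parsed JSON) and float32 payload of declared length.
read_container <- function(path, expect_format) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- raw(0)
  repeat {
    chunk <- readBin(con, "raw", n = 65536L)
    if (!length(chunk)) stop("no header line found in '", path, "'", call. = FALSE)
    hdr_raw <- c(hdr_raw, chunk)
    nl <- which(hdr_raw == as.raw(0x0a))
    if (length(nl)) { nl <- nl[1]; break }
  }
  header <- try(jsonlite::fromJSON(rawToChar(hdr_raw[seq_len(nl - 1L)])),
                silent = TRUE)
  if (inherits(header, "try-error"))
    stop("malformed JSON header in '", path, "'", call. = FALSE)
  if (!identical(header$format, expect_format))
    stop("container format mismatch: expected '", expect_format, "', got '",
         header$format, "'", call. = FALSE)
  if (!identical(as.character(header$version), CONTAINER_VERSION))
    stop("container version mismatch: expected ", CONTAINER_VERSION,
         ", got ", header$version, call. = FALSE)
  if (!identical(header$dtype, "float32-le"))
    stop("unsupported payload dtype '", header$dtype, "'", call. = FALSE)
  n_expect <- prod(as.numeric(header$shape))
  seek(con, where = nl, origin = "start")
  payload <- readBin(con, "numeric", n = n_expect + 1L, size = 4L,
                     endian = "little")
  if (length(payload) != n_expect)
    stop("payload length mismatch in '", path, "': expected ",
         n_expect * 4L, " bytes (", n_expect, " float32 values), found ",
         length(payload) * 4L, " bytes", call. = FALSE)
  list(header = header, payload = payload)
}

#' Write an RF ensemble container
#'
#' Serialises an [rf_ensemble()] to a two-part container: a single-line UTF-8
#' JSON header (all acquisition-config fields, a format-version string, the
#' sample dtype `"float32-le"` and the shape) followed by the sample payload
#' as little-endian 32-bit floats, slow-time major (each pulse's echo line is
#' contiguous, matching acquisition order). Round-trips bit-exactly through
#' [read_rf()] for float32-representable inputs.
#'
#' @param ensemble an `rf_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rf <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "rf_ensemble"))
  header <- list(
    format = RF_FORMAT, version = CONTAINER_VERSION, dtype = "float32-le",
    shape = c(ensemble$config$n_slow, ensemble$config$n_fast),
    config = config_to_list(ensemble$config)
  )
  # slow-time major: transpose so each row (pulse line) is contiguous
  write_container(path, header, as.numeric(t(ensemble$samples)))
  invisible(path)
}

#' Read an RF ensemble container
#'
#' Inverse of [write_rf()]: validates the header (format, version, dtype,
#' shape and config invariants) and reconstructs the `rf_ensemble`.
#'
#' @param path file written by [write_rf()].
#' @return an `rf_ensemble`.
#' @export
read_rf <- function(path) {
  ct <- read_container(path, RF_FORMAT)
  shape <- as.integer(ct$header$shape)
  if (length(shape) != 2L)
    stop("RF container shape must have 2 dimensions", call. = FALSE)
  cfg <- config_from_list(as.list(ct$header$config))
  if (cfg$n_slow != shape[1] || cfg$n_fast != shape[2])
    stop("header shape [", shape[1], ", ", shape[2],
         "] disagrees with config (n_slow = ", cfg$n_slow,
         ", n_fast = ", cfg$n_fast, ")", call. = FALSE)
  samples <- matrix(ct$payload, nrow = shape[1], ncol = shape[2], byrow = TRUE)
  rf_ensemble(cfg, samples)
}

#' Write a matrix container (sonograms and other gridded results)
#'
#' Same two-part layout as the RF container: JSON header (format
#' `"pwdoppler-matrix"`, version, dtype, shape, named axis vectors and free
#' metadata) followed by the matrix as little-endian float32, row-major.
#'
#' @param mat numeric matrix.
#' @param path output file path.
#' @param axes named list of numeric axis vectors; lengths must match
#'   `dim(mat)` in order (rows first).
#' @param meta named list of scalar metadata stored verbatim in the header.
#' @return `path`, invisibly.
#' @export
write_matrix_container <- function(mat, path, axes = list(), meta = list()) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (length(axes)) {
    lens <- vapply(axes, length, integer(1))
    if (!all(lens == dim(mat)[seq_along(axes)]))
      stop("axis lengths must match matrix dimensions", call. = FALSE)
  }
  header <- list(format = MATRIX_FORMAT, version = CONTAINER_VERSION,
                 dtype = "float32-le", shape = dim(mat),
                 axes = axes, meta = meta)
  write_container(path, header, as.numeric(t(mat)))
  invisible(path)
}

#' Read a matrix container
#'
#' @param path file written by [write_matrix_container()].
#' @return list with elements `matrix`, `axes`, `meta`.
#' @export
read_matrix_container <- function(path) {
  ct <- read_container(path, MATRIX_FORMAT)
  shape <- as.integer(ct$header$shape)
  list(
    matrix = matrix(ct$payload, nrow = shape[1], ncol = shape[2], byrow = TRUE),
    axes = lapply(ct$header$axes, as.numeric),
    meta = ct$header$meta
  )
}
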