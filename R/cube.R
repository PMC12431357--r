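#' Radar cube: slow-time x fast-time echo matrix with acquisition metadata
#'
#' The central container of the package. Rows index slow time (successive
#' frames), columns index fast time (range bins). Data may be real
#' (RF-like) or complex baseband; phase-dependent operations require
#' complex input. Bin and frame indices are 1-based throughout.
#'
#' @param data numeric or complex matrix, frames x bins.
#' @param frame_rate pulse repetition (frame) rate in Hz.
#' @param bin_spacing range extent of one fast-time bin, metres.
#' @param center_frequency radar centre frequency in Hz.
#' @param t0_offset range of the first bin, metres.
#' @return object of class `radar_cube` with fields `data`, `frame_rate`,
#'   `bin_spacing`, `center_frequency`, `wavelength` (derived, c/fc) and
#'   `t0_offset`.
#' @examples
#' cube <- radar_cube(matrix(rnorm(40), 10, 4), frame_rate = 17,
#'                    bin_spacing = 0.0514, center_frequency = 7.29e9)
#' n_frames(cube)
#' @export
radar_cube <- function(data, frame_rate, bin_spacing, center_frequency,
                       t0_offset = 0) {
  data <- as.matrix(data)
  cube <- structure(
    list(data = data,
         frame_rate = frame_rate,
         bin_spacing = bin_spacing,
         center_frequency = center_frequency,
         wavelength = C_LIGHT / center_frequency,
         t0_offset = t0_offset),
    class = "radar_cube")
  validate_radar_cube(cube)
}

#' Validate a radar cube
#'
#' Checks the container invariants: at least 2 frames and 2 bins, positive
#' frame rate and bin spacing, finite data, and consistency of the stored
#' wavelength with the centre frequency (to 1e-6 relative).
#'
#' @param cube a [radar_cube].
#' @return the cube, invisibly validated (returned unchanged).
#' @export
validate_radar_cube <- function(cube) {
  d <- cube$data
  if (!is.matrix(d) || nrow(d) < 2 || ncol(d) < 2) {
    uv_stop("cube data must be a matrix with >= 2 frames and >= 2 bins",
            "uwbvitals_schema_error")
  }
  for (f in c("frame_rate", "bin_spacing", "center_frequency")) {
    v <- cube[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      uv_stop(sprintf("metadata field '%s' must be a positive finite scalar", f),
              "uwbvitals_schema_error")
    }
  }
  rel <- abs(cube$wavelength * cube$center_frequency - C_LIGHT) / C_LIGHT
  if (!is.finite(rel) || rel > 1e-6) {
    uv_stop("wavelength inconsistent with center_frequency (c = lambda * fc)",
            "uwbvitals_schema_error")
  }
  if (!all(is.finite(Re(d))) || (is.complex(d) && !all(is.finite(Im(d))))) {
    uv_stop("cube data contains non-finite values", "uwbvitals_data_error")
  }
  cube
}

#' @rdname radar_cube
#' @export
n_frames <- function(cube) nrow(cube$data)

#' @rdname radar_cube
#' @export
n_bins <- function(cube) ncol(cube$data)

#' @rdname radar_cube
#' @export
is_complex_cube <- function(cube) is.complex(cube$data)

#' Range (metres) of each fast-time bin
#' @param cube a [radar_cube].
#' @return numeric vector of bin-centre ranges.
#' @export
bin_ranges <- function(cube) {
  cube$t0_offset + (seq_len(n_bins(cube)) - 1) * cube$bin_spacing
}

# Replace the data matrix, keeping metadata.
cube_with_data <- function(cube, data) {
  cube$data <- data
  validate_radar_cube(cube)
}

#' @export
print.radar_cube <- function(x, ...) {
  cat(sprintf("<radar_cube> %d frames x %d bins (%s)\n",
              n_frames(x), n_bins(x),
              if (is_complex_cube(x)) "complex baseband" else "real"))
  cat(sprintf("  frame rate %g Hz | bin spacing %g m | fc %.4g GHz (lambda %.4g m)\n",
              x$frame_rate, x$bin_spacing, x$center_frequency / 1e9, x$wavelength))
  cat(sprintf("  range span %.3f - %.3f m\n",
              x$t0_offset, x$t0_offset + n_bins(x) * x$bin_spacing))
  invisible(x)
}

cube_meta_path <- function(path) {
  paste0(sub("\\.csv$", "", path), ".meta.json")
}

fmt_full <- function(x) formatC(x, digits = 17, format = "g")

#' Write a radar cube to disk
#'
#' The `csv` container stores one frame per row with full (17 significant
#' digit) precision, complex data as interleaved re/im columns, and the
#' metadata in a JSON sidecar `<name>.meta.json` with keys
#' `frame_rate_hz`, `bin_spacing_m`, `center_frequency_hz`, `t0_offset_m`
#' and `complex`. Reading the pair back reproduces the data bit-exactly.
#'
#' @param cube a [radar_cube].
#' @param path output file path.
#' @param format container format; only `"csv"` (CSV + JSON sidecar) is
#'   supported.
#' @return the path, invisibly.
#' @export
write_cube <- function(cube, path, format = c("csv", "hdf5", "npz")) {
  format <- match.arg(format)
  if (format != "csv") {
    uv_stop(sprintf("format '%s' is not supported; use 'csv' (CSV + JSON sidecar)",
                    format), "uwbvitals_config_error")
  }
  validate_radar_cube(cube)
  d <- cube$data
  if (is.complex(d)) {
    flat <- matrix(0, nrow(d), 2 * ncol(d))
    flat[, seq(1, 2 * ncol(d), by = 2)] <- Re(d)
    flat[, seq(2, 2 * ncol(d), by = 2)] <- Im(d)
  } else {
    flat <- d
  }
  ok <- tryCatch({
    utils::write.table(matrix(fmt_full(flat), nrow(flat), ncol(flat)),
                       file = path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) uv_stop(sprintf("cannot write to '%s'", path), "uwbvitals_io_error")
  meta <- list(frame_rate_hz = cube$frame_rate,
               bin_spacing_m = cube$bin_spacing,
               center_frequency_hz = cube$center_frequency,
               t0_offset_m = cube$t0_offset,
               complex = is.complex(d),
               layout = "frames_by_bins")
  jsonlite::write_json(meta, cube_meta_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a radar cube from disk
#'
#' Counterpart of [write_cube()]. Orientation is always frames x bins
#' regardless of the on-disk layout flag.
#'
#' @param path path of the data file written by [write_cube()].
#' @param format container format; only `"csv"` is supported.
#' @return a validated [radar_cube].
#' @export
read_cube <- function(path, format = c("csv", "hdf5", "npz")) {
  format <- match.arg(format)
  if (format != "csv") {
    uv_stop(sprintf("format '%s' is not supported; use 'csv' (CSV + JSON sidecar)",
                    format), "uwbvitals_config_error")
  }
  if (!file.exists(path)) {
    uv_stop(sprintf("file '%s' does not exist", path), "uwbvitals_io_error")
  }
  mpath <- cube_meta_path(path)
  if (!file.exists(mpath)) {
    uv_stop(sprintf("metadata sidecar '%s' is missing", mpath), "uwbvitals_schema_error")
  }
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  for (key in c("frame_rate_hz", "bin_spacing_m", "center_frequency_hz")) {
    if (is.null(meta[[key]])) {
      uv_stop(sprintf("metadata field '%s' is missing from '%s'", key, mpath),
              "uwbvitals_schema_error")
    }
  }
  raw <- as.matrix(utils::read.csv(path, header = FALSE, colClasses = "numeric"))
  dimnames(raw) <- NULL
  if (!all(is.finite(raw))) {
    uv_stop("cube data contains non-finite values", "uwbvitals_data_error")
  }
  is_cplx <- isTRUE(meta$complex)
  if (is_cplx) {
    nb <- ncol(raw) / 2
    data <- complex(real = raw[, seq(1, 2 * nb, by = 2)],
                    imaginary = raw[, seq(2, 2 * nb, by = 2)])
    data <- matrix(data, nrow(raw), nb)
  } else {
    data <- raw
  }
  radar_cube(data,
             frame_rate = meta$frame_rate_hz,
             bin_spacing = meta$bin_spacing_m,
             center_frequency = meta$center_frequency_hz,
             t0_offset = if (is.null(meta$t0_offset_m)) 0 else meta$t0_offset_m)
}

#' One-dimensional physiological signal with a sampling rate
#'
#' Plain carrier for slow-time waveforms and reference traces (e.g. a
#' bandage-sensor respiration recording).
#'
#' @param samples numeric vector.
#' @param rate sampling rate, Hz.
#' @param label free-text description.
#' @return object of class `signal_trace`.
#' @export
signal_trace <- function(samples, rate, label = "") {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    uv_stop("rate must be a positive scalar", "uwbvitals_schema_error")
  }
  if (!all(is.finite(samples))) {
    uv_stop("signal contains non-finite samples", "uwbvitals_data_error")
  }
  structure(list(samples = samples, rate = rate, label = as.character(label)),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %d samples @ %g Hz (%.3g s)%s\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              if (nzchar(x$label)) paste0(" - ", x$label) else ""))
  invisible(x)
}

#' @rdname signal_trace
#' @param trace a `signal_trace`.
#' @param path file path for the two-column CSV (`time_s,value`).
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "signal_trace"))
  n <- length(trace$samples)
  df <- data.frame(time_s = fmt_full((seq_len(n) - 1) / trace$rate),
                   value = fmt_full(trace$samples))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname signal_trace
#' @export
read_trace <- function(path, label = "") {
  if (!file.exists(path)) {
    uv_stop(sprintf("file '%s' does not exist", path), "uwbvitals_io_error")
  }
  df <- utils::read.csv(path)
  if (ncol(df) < 2) uv_stop("trace CSV needs columns time_s,value", "uwbvitals_schema_error")
  dt <- stats::median(diff(df[[1]]))
  signal_trace(df[[2]], rate = 1 / dt, label = label)
}
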