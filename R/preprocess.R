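#' Envelope alignment (coarse range-migration compensation)
#'
#' Platform motion shifts the target echo across range bins over slow
#' time. Each frame's magnitude envelope is cross-correlated with the
#' reference envelope over integer lags in `-max_lag:max_lag`; the frame
#' is shifted by the maximizing lag, with out-shifted samples
#' zero-filled. By default the reference is the first frame's envelope,
#' which anchors every frame to a fixed range: correlating only against
#' the previous frame cannot correct drifts slower than one bin per
#' frame (the per-step lag rounds to zero), so the fixed-reference form
#' is the default and `reference = "previous"` is available for
#' step-like migrations.
#'
#' @param cube a [radar_cube] with at least 2 frames.
#' @param max_lag largest shift (bins) searched.
#' @param reference `"first"` (default) or `"previous"`.
#' @return object of class `alignment_result`: `aligned` (a
#'   [radar_cube]), `shifts` (integer per-frame bin shifts, `shifts[1] ==
#'   0`), and `phase_corrections` (filled by [phase_compensate()]).
#' @export
envelope_align <- function(cube, max_lag = 10, reference = c("first", "previous")) {
  validate_radar_cube(cube)
  reference <- match.arg(reference)
  nf <- n_frames(cube)
  nb <- n_bins(cube)
  env <- abs(Mod(cube$data))
  lags <- -max_lag:max_lag
  shifts <- integer(nf)
  out <- cube$data
  ref_env <- env[1, ]
  skipped <- 0L
  for (k in 2:nf) {
    cur <- env[k, ]
    if (all(cur == 0)) {
      shifts[k] <- shifts[k - 1]
      skipped <- skipped + 1L
    } else {
      score <- vapply(lags, function(l) {
        i <- seq_len(nb)
        j <- i + l
        ok <- j >= 1 & j <= nb
        sum(ref_env[i[ok]] * cur[j[ok]])
      }, numeric(1))
      best <- which(score == max(score))
      shifts[k] <- lags[best[which.min(abs(lags[best]))]]
    }
    out[k, ] <- shift_row(cube$data[k, ], shifts[k])
    if (reference == "previous") ref_env <- abs(Mod(out[k, ]))
  }
  if (skipped > 0) {
    uv_warn(sprintf("%d all-zero frame(s) skipped during alignment (shift carried forward)",
                    skipped), "uwbvitals_alignment_warning")
  }
  structure(list(aligned = cube_with_data(cube, out),
                 shifts = shifts,
                 phase_corrections = NULL),
            class = "alignment_result")
}

# Shift a fast-time row left by s bins (aligned[i] = raw[i + s]), zero fill.
shift_row <- function(x, s) {
  n <- length(x)
  zero <- if (is.complex(x)) 0 + 0i else 0
  out <- rep(zero, n)
  i <- seq_len(n)
  j <- i + s
  ok <- j >= 1 & j <= n
  out[i[ok]] <- x[j[ok]]
  out
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %d frames, shifts in [%d, %d]\n",
              length(x$shifts), min(x$shifts), max(x$shifts)))
  invisible(x)
}

#' Phase compensation (fine range-migration compensation)
#'
#' After integer-bin envelope alignment a residual sub-bin platform
#' phase remains on every bin. The weighted average of the first `Na`
#' aligned frames serves as a benchmark; each frame is rotated by minus
#' the circular mean of its bin-wise phase differences to the benchmark
#' (magnitude-weighted, so strong scatterers dominate). By default only
#' prominent bins (mean envelope above `mask_factor` times the median)
#' enter the mean, which keeps diffuse clutter from polluting the
#' estimate.
#'
#' @param aligned an `alignment_result` (or complex [radar_cube]).
#' @param Na number of leading frames averaged into the benchmark.
#' @param weights optional non-negative per-frame weights for the
#'   benchmark (default uniform).
#' @param mask_factor prominence threshold for benchmark bins; `0` uses
#'   all bins.
#' @return the compensated [radar_cube]; per-frame corrections (radians,
#'   wrapped to (-pi, pi]) in attribute `"phase_corrections"`.
#' @export
phase_compensate <- function(aligned, Na = 10, weights = NULL, mask_factor = 3) {
  cube <- if (inherits(aligned, "alignment_result")) aligned$aligned else aligned
  validate_radar_cube(cube)
  if (!is_complex_cube(cube)) {
    uv_stop("phase compensation requires complex baseband data; skip fine compensation for real cubes",
            "uwbvitals_type_error")
  }
  nf <- n_frames(cube)
  Na <- min(Na, nf)
  if (Na < 1) uv_stop("Na must be >= 1", "uwbvitals_param_error")
  if (is.null(weights)) weights <- rep(1, Na)
  if (length(weights) < Na || any(weights < 0) || sum(weights[seq_len(Na)]) == 0) {
    uv_stop("weights must be non-negative with positive sum over the first Na frames",
            "uwbvitals_param_error")
  }
  w <- weights[seq_len(Na)] / sum(weights[seq_len(Na)])

  mean_env <- colMeans(Mod(cube$data))
  mask <- if (mask_factor > 0) mean_env > mask_factor * stats::median(mean_env) else rep(TRUE, length(mean_env))
  if (!any(mask)) mask <- rep(TRUE, length(mean_env))

  # The benchmark frames are phase-aligned to each other before they are
  # averaged: under platform motion the common phase of even a few
  # consecutive frames spans many radians, and a naive average of raw
  # frames sums phasors destructively into a meaningless reference.
  est_phi <- function(frame, ref) Arg(sum(frame[mask] * Conj(ref[mask])))
  bench <- w[1] * cube$data[1, ]
  if (Na > 1) {
    for (k in 2:Na) {
      psi <- est_phi(cube$data[k, ], bench)
      bench <- bench + w[k] * cube$data[k, ] * exp(-1i * psi)
    }
  }
  phi <- vapply(seq_len(nf), function(k) est_phi(cube$data[k, ], bench), numeric(1))
  out <- cube$data * exp(-1i * phi)
  res <- cube_with_data(cube, out)
  attr(res, "phase_corrections") <- phi
  res
}

#' Prominent scatterer clusters in a radar cube
#'
#' Groups range bins whose mean magnitude envelope exceeds `factor`
#' times the median into clusters of adjacent bins (bridging gaps up to
#' `gap` bins). Scalar phase compensation needs at least two such
#' clusters - a vital target plus a static reference - to have a
#' benchmark that is not the target itself; with a lone scatterer the
#' compensation phase would track (and cancel) the target's own motion.
#'
#' @param cube a [radar_cube].
#' @param factor prominence threshold relative to the median envelope.
#' @param gap largest gap (bins) bridged within one cluster.
#' @return list of integer vectors (bin indices), one per cluster.
#' @export
prominent_clusters <- function(cube, factor = 3, gap = 2) {
  env <- colMeans(Mod(cube$data))
  mask <- env > factor * stats::median(env)
  idx <- which(mask)
  if (!length(idx)) return(list())
  breaks <- c(0, which(diff(idx) > gap + 1), length(idx))
  lapply(seq_len(length(breaks) - 1), function(k) {
    idx[(breaks[k] + 1):breaks[k + 1]]
  })
}

#' DC drift removal along slow time
#'
#' Per range bin, subtracts the length-`window` moving average of the
#' slow-time series (shrinking windows at the edges), cancelling
#' static-object DC components and slow baseline drift while passing the
#' physiological band.
#'
#' @param cube a [radar_cube].
#' @param window moving-average length in frames (default 100).
#' @return the DC-removed [radar_cube].
#' @export
remove_dc <- function(cube, window = 100) {
  validate_radar_cube(cube)
  if (window < 2) uv_stop("window must be >= 2", "uwbvitals_param_error")
  if (window > n_frames(cube)) {
    uv_stop("window exceeds the number of frames", "uwbvitals_param_error")
  }
  out <- apply(cube$data, 2, function(col) col - moving_avg(col, as.integer(window)))
  cube_with_data(cube, out)
}

#' Locate the human target range bin
#'
#' Sums the squared magnitude of the DC-removed slow-time signal in each
#' range bin; the bin with the maximum energy is the target position
#' (ties broken to the lowest index). Bin indices are 1-based.
#'
#' @param cube a DC-removed [radar_cube].
#' @return list with `bin` (integer index) and `energy` (per-bin profile).
#' @export
locate_target <- function(cube) {
  validate_radar_cube(cube)
  energy <- colSums(Mod(cube$data)^2)
  if (all(energy == 0)) {
    uv_stop("all-zero cube: no target found", "uwbvitals_target_error")
  }
  list(bin = which.max(energy), energy = energy)
}

#' Extract slow-time channels around the target bin
#'
#' Returns the `2 * half_width + 1` slow-time signals from the bins
#' centred on `center`, ordered by bin. For complex cubes the channel
#' signal is the unwrapped phase (radians), which is linear in target
#' displacement; for real cubes the raw amplitude is used. Windows that
#' exceed the cube edge are truncated with a warning.
#'
#' @param cube a [radar_cube].
#' @param center target bin (1-based).
#' @param half_width bins on each side (default 2, i.e. 5 channels).
#' @param type `"auto"` (phase when complex), `"phase"`, or `"amplitude"`.
#' @return object of class `channel_set`: `signals` (channels x frames
#'   matrix), `rate`, `bin_labels`, `type`.
#' @export
extract_channels <- function(cube, center, half_width = 2,
                             type = c("auto", "phase", "amplitude")) {
  validate_radar_cube(cube)
  type <- match.arg(type)
  nb <- n_bins(cube)
  if (center < 1 || center > nb) {
    uv_stop("center bin outside the cube", "uwbvitals_param_error")
  }
  want <- (center - half_width):(center + half_width)
  bins <- want[want >= 1 & want <= nb]
  if (length(bins) < length(want)) {
    uv_warn(sprintf("channel window truncated at the cube edge: %d of %d channels",
                    length(bins), length(want)), "uwbvitals_edge_warning")
  }
  if (type == "auto") type <- if (is_complex_cube(cube)) "phase" else "amplitude"
  if (type == "phase" && !is_complex_cube(cube)) {
    uv_stop("phase channels require complex baseband data", "uwbvitals_type_error")
  }
  sig <- t(apply(cube$data[, bins, drop = FALSE], 2, function(col) {
    if (type == "phase") phase_unwrap(Arg(col)) else Mod(col)
  }))
  channel_set(sig, rate = cube$frame_rate, bin_labels = bins, type = type)
}

#' Slow-time channel set
#'
#' The a x n observed-signal matrix handed to blind source separation:
#' `a` channels (rows) by `n` slow-time frames (columns).
#'
#' @param signals channels x frames numeric matrix.
#' @param rate slow-time sampling rate, Hz.
#' @param bin_labels 1-based range-bin labels of the rows.
#' @param type signal type tag.
#' @return object of class `channel_set`.
#' @export
channel_set <- function(signals, rate, bin_labels = seq_len(nrow(signals)),
                        type = "amplitude") {
  signals <- as.matrix(signals)
  if (!all(is.finite(signals))) {
    uv_stop("channel signals contain non-finite values", "uwbvitals_data_error")
  }
  if (rate <= 0) uv_stop("rate must be positive", "uwbvitals_schema_error")
  structure(list(signals = signals, rate = rate,
                 bin_labels = bin_labels, type = type),
            class = "channel_set")
}

#' @export
print.channel_set <- function(x, ...) {
  cat(sprintf("<channel_set> %d channels x %d frames @ %g Hz (%s), bins %s\n",
              nrow(x$signals), ncol(x$signals), x$rate, x$type,
              paste(x$bin_labels, collapse = ",")))
  invisible(x)
}
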