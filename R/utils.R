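# Internal helpers shared across modules.

C_LIGHT <- 299792458  # m/s

uv_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "uwbvitals_error")))
}

uv_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "uwbvitals_warning")))
}

#' Unwrap a phase sequence
#'
#' Removes 2*pi jumps from a wrapped phase series so that successive
#' differences are restricted to (-pi, pi].
#'
#' @param p numeric vector of phase angles in radians.
#' @return numeric vector of the same length with jumps removed.
#' @export
phase_unwrap <- function(p) {
  if (length(p) < 2) return(p)
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d))
}

# Forward extrapolation of a record by `npad` samples with a Burg AR
# model. Sinusoidal content continues exactly (each tone needs only an
# AR(2) pair), so extensions built this way avoid the value/derivative
# kinks of reflection padding.
ar_extend <- function(v, npad, max_order = 30L) {
  ords <- unique(pmin(c(2L, 4L, 8L, 16L, max_order), max(2L, length(v) %/% 3L)))
  # smallest order whose prediction error matches the best: forcing a
  # high order on nearly noiseless data plants spurious near-unit poles
  # that wander over long extrapolation horizons
  fits <- lapply(ords, function(k) {
    tryCatch(stats::ar.burg(v, aic = FALSE, order.max = k, demean = TRUE),
             error = function(e) NULL)
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) return(rep(v[length(v)], npad))
  vp <- vapply(fits, function(f) f$var.pred, numeric(1))
  tol <- 1.1 * min(vp) + 1e-12 * stats::var(v)
  fit <- fits[[which(vp <= tol)[1]]]
  if (!length(fit$ar)) return(rep(v[length(v)], npad))
  co <- ar_stabilize(fit$ar)
  p <- length(co)
  buf <- c(v[seq.int(length(v) - p + 1L, length(v))] - fit$x.mean, numeric(npad))
  for (k in seq_len(npad)) buf[p + k] <- sum(co * buf[p + k - seq_len(p)])
  buf[p + seq_len(npad)] + fit$x.mean
}

# Reflect any predictor poles outside the unit circle back inside
# (1/conj(root)); high-order fits on nearly noiseless data can go
# numerically unstable, and reflection bounds the extrapolation while
# preserving the magnitude spectrum.
ar_stabilize <- function(co) {
  rts <- tryCatch(polyroot(c(-rev(co), 1)), error = function(e) NULL)
  if (is.null(rts) || !any(Mod(rts) > 1 + 1e-9)) return(co)
  bad <- Mod(rts) > 1
  rts[bad] <- 1 / Conj(rts[bad])
  coefs <- 1
  for (r in rts) coefs <- c(coefs, 0) - r * c(0, coefs)  # monic, decreasing degree
  -Re(coefs[-1])
}

# Zero-phase (forward-backward) IIR filtering. The record is extended on
# both sides before filtering so the filter reaches steady state ahead
# of the data. Two extension schemes:
#
# * "model" (default): content at the frequencies in `tone_omega`
#   (radians per sample; used for notch frequencies) plus any offset and
#   linear trend is captured by least-squares projection and continued
#   exactly -- a tone a narrow notch must annihilate then produces no
#   start-up transient inside the record -- while the remainder is
#   odd-reflected. Projection and reflection are both linear in the
#   data, so the whole operator stays exactly linear.
# * "ar": Burg autoregressive extrapolation, which continues whatever
#   strong oscillations the record holds without being told their
#   frequencies (used by the band-pass stage, where a dominant stop-band
#   respiration line would otherwise ring across the pass band). Signal-
#   adaptive, hence not exactly linear.
#
# Padding length follows the slowest filter pole.
zero_phase_filter <- function(b, a, x, tone_omega = NULL,
                              extension = c("model", "ar")) {
  extension <- match.arg(extension)
  n <- length(x)
  r <- 0
  if (length(a) > 1) {
    r <- tryCatch(max(Mod(polyroot(rev(a / a[1])))), error = function(e) 0)
  }
  npad <- ceiling(6 / max(1 - min(r, 0.9995), 1e-4))
  npad <- max(npad, 3 * (max(length(a), length(b)) - 1))
  npad <- min(npad, 12000L)
  if (npad > 0 && n > 10 && extension == "ar") {
    xe <- c(rev(ar_extend(rev(x), npad)), x, ar_extend(x, npad))
  } else if (npad > 0 && n > 10) {
    k <- seq_len(n)
    basis <- cbind(1, k / n)
    for (w in tone_omega) basis <- cbind(basis, sin(w * k), cos(w * k))
    fit <- stats::lm.fit(basis, x)
    res <- fit$residuals
    model_at <- function(kk) {
      bb <- cbind(1, kk / n)
      for (w in tone_omega) bb <- cbind(bb, sin(w * kk), cos(w * kk))
      as.numeric(bb %*% fit$coefficients)
    }
    # the model continues arbitrarily far; the remainder reflection is
    # limited to n - 1 samples, with zeros beyond (any join discontinuity
    # sits a full record away from the data and decays before reaching it)
    nref <- min(npad, n - 1L)
    pre <- model_at(seq.int(1 - npad, 0)) +
      c(numeric(npad - nref), 2 * res[1] - res[(nref + 1):2])
    post <- model_at(seq.int(n + 1, n + npad)) +
      c(2 * res[n] - res[(n - 1):(n - nref)], numeric(npad - nref))
    xe <- c(pre, x, post)
  } else {
    npad <- 0L
    xe <- x
  }
  y <- as.numeric(signal::filter(b, a, xe))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[npad + seq_len(n)]
}

#' Zero-padded magnitude spectrum
#'
#' Magnitude of the discrete Fourier transform of `x` zero-padded to
#' `pad` times its length (no window), returned for the non-negative
#' frequencies only.
#'
#' @param x numeric vector.
#' @param rate sampling rate in Hz.
#' @param pad integer zero-padding factor (default 8).
#' @return list with elements `freq` (Hz) and `mag`.
#' @export
spectrum_mag <- function(x, rate, pad = 8) {
  n <- length(x)
  if (n < 2) uv_stop("need at least 2 samples for a spectrum", "uwbvitals_param_error")
  nfft <- max(2L, as.integer(round(pad)) * n)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  half <- floor(nfft / 2) + 1L
  list(freq = (seq_len(half) - 1) * rate / nfft, mag = Mod(X[seq_len(half)]))
}

# Coerce a signal_trace or numeric vector (+ rate) to list(samples, rate).
slow_signal <- function(x, rate = NULL) {
  if (inherits(x, "signal_trace")) {
    list(samples = x$samples, rate = x$rate, label = x$label)
  } else {
    if (is.null(rate)) {
      uv_stop("`rate` must be supplied for a plain numeric signal", "uwbvitals_param_error")
    }
    list(samples = as.numeric(x), rate = rate, label = "")
  }
}

# Return a result shaped like the input signal (signal_trace in, trace out).
rewrap_signal <- function(samples, template) {
  if (inherits(template, "signal_trace")) {
    signal_trace(samples, template$rate, template$label)
  } else {
    samples
  }
}

#' Locate the dominant spectral peak in a frequency band
#'
#' Argmax of the zero-padded magnitude spectrum restricted to `band`,
#' optionally refined by parabolic interpolation through the peak bin
#' and its neighbours (three-point quadratic fit). The refinement
#' resolves rates far below the raw transform grid, which is what makes
#' four-decimal rate estimates from a 30 s record meaningful. The
#' series mean is removed before the transform so that spectral leakage
#' from a DC offset cannot masquerade as a peak.
#'
#' @param x a [signal_trace] or numeric vector.
#' @param rate sampling rate in Hz (ignored when `x` is a trace).
#' @param band length-2 numeric, Hz.
#' @param pad zero-padding factor.
#' @param refine logical; apply parabolic peak interpolation.
#' @return peak frequency in Hz.
#' @export
estimate_rate <- function(x, rate = NULL, band = c(0.1, 0.6), pad = 8,
                          refine = TRUE) {
  s <- slow_signal(x, rate)
  sp <- spectrum_mag(s$samples - mean(s$samples), s$rate, pad)
  idx <- which(sp$freq >= band[1] & sp$freq <= band[2])
  if (length(idx) < 1) uv_stop("band contains no spectral points", "uwbvitals_param_error")
  m <- sp$mag[idx]
  if (max(m) <= 0 || diff(range(m)) <= 1e-12 * max(m)) {
    uv_stop("no spectral peak found in band (flat spectrum)", "uwbvitals_peak_error")
  }
  k <- idx[which.max(m)]
  f <- sp$freq[k]
  if (refine && k > 1 && k < length(sp$mag)) {
    f <- f + peak_refine(sp$mag[(k - 1):(k + 1)]) * (sp$freq[2] - sp$freq[1])
  }
  f
}

# Three-point parabolic interpolation offset (in bins, in [-0.5, 0.5]).
peak_refine <- function(m3) {
  den <- m3[1] - 2 * m3[2] + m3[3]
  if (den >= 0) return(0)                 # not a local maximum
  max(-0.5, min(0.5, 0.5 * (m3[1] - m3[3]) / den))
}

# Centered moving average with shrinking windows at the edges.
# Works for real and complex input.
moving_avg <- function(x, w) {
  n <- length(x)
  h1 <- (w - 1L) %/% 2L
  h2 <- w - 1L - h1
  cs <- cumsum(x)
  lo <- pmax(seq_len(n) - h1, 1L)
  hi <- pmin(seq_len(n) + h2, n)
  left <- rep(if (is.complex(x)) 0 + 0i else 0, n)
  has_left <- lo > 1L
  left[has_left] <- cs[lo[has_left] - 1L]
  (cs[hi] - left) / (hi - lo + 1)
}
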