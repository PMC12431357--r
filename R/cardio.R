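#' Band-pass filter for the heartbeat band
#'
#' Zero-phase (forward-backward) Butterworth band-pass with the normal
#' adult heart-rate band 0.85-3.3 Hz as default cutoffs. The underlying
#' filter is a 4th-order maximally-flat IIR; the two-pass application
#' squares its magnitude response, so pass-band ripple stays well under
#' 1 dB and out-of-band rejection exceeds 20 dB an octave out.
#'
#' @param x a [signal_trace] or numeric vector.
#' @param rate sampling rate, Hz (for numeric input).
#' @param low,high cutoff frequencies, Hz.
#' @return filtered signal, same type as input.
#' @export
bandpass_heart <- function(x, rate = NULL, low = 0.85, high = 3.3) {
  s <- slow_signal(x, rate)
  if (high >= s$rate / 2) {
    uv_stop("upper cutoff must be below the Nyquist frequency", "uwbvitals_param_error")
  }
  if (low <= 0 || low >= high) {
    uv_stop("need 0 < low < high", "uwbvitals_param_error")
  }
  bf <- signal::butter(2, c(low, high) / (s$rate / 2), type = "pass")
  rewrap_signal(zero_phase_filter(bf$b, bf$a, s$samples, extension = "ar"), x)
}

#' Locate respiratory harmonics inside the heart band
#'
#' Estimates the respiratory fundamental as the argmax of the
#' zero-padded magnitude spectrum in `fund_band`, then returns the
#' harmonics `k * f0` for the requested orders that fall inside `band`.
#' Orders whose harmonic lies below the band edge are silently skipped
#' (with breathing near 0.3 Hz the 1st and 2nd harmonics sit below the
#' 0.85 Hz heart-band edge, leaving the 3rd-5th).
#'
#' @param respiration a [signal_trace] or numeric vector.
#' @param rate sampling rate, Hz.
#' @param orders integer harmonic orders (default 3:5).
#' @param band heart band in Hz; harmonics outside are dropped.
#' @param fund_band search band for the fundamental, Hz.
#' @param pad zero-padding factor of the spectrum.
#' @return numeric vector of harmonic frequencies (Hz), with the
#'   fundamental in attribute `"fundamental"`.
#' @export
locate_harmonics <- function(respiration, rate = NULL, orders = 3:5,
                             band = c(0.85, 3.3), fund_band = c(0.1, 0.6),
                             pad = 8) {
  s <- slow_signal(respiration, rate)
  sp <- spectrum_mag(s$samples - mean(s$samples), s$rate, pad)
  idx <- which(sp$freq >= fund_band[1] & sp$freq <= fund_band[2])
  if (!length(idx)) uv_stop("fundamental band is empty", "uwbvitals_param_error")
  peak <- max(sp$mag[idx])
  if (peak <= 3 * stats::median(sp$mag)) {
    uv_stop("no in-band fundamental peak above 3x the median spectral magnitude",
            "uwbvitals_fundamental_error")
  }
  k <- idx[which.max(sp$mag[idx])]
  f0 <- sp$freq[k]
  if (k > 1 && k < length(sp$mag)) {
    f0 <- f0 + peak_refine(sp$mag[(k - 1):(k + 1)]) * (sp$freq[2] - sp$freq[1])
  }
  h <- orders * f0
  keep <- h >= band[1] & h <= band[2]
  structure(h[keep], fundamental = f0, orders = orders[keep])
}

#' Design a feedback notch filter
#'
#' A second-order notch `G(z) = (1 - 2 cos(w*) z^-1 + z^-2) /
#' (1 - 2 rho cos(w*) z^-1 + rho^2 z^-2)` wrapped in the feedback form
#' `H(z) = (1 + alpha) G(z) / (1 + alpha G(z))`, which sharpens the
#' notch without moving its zero: the gain at `w*` is exactly 0 for any
#' feedback gain, while increasing `alpha` shrinks the -3 dB bandwidth.
#' The closed-loop form stays a second-order rational filter:
#' numerator `(1 + alpha) b_G`, denominator `a_G + alpha b_G`.
#'
#' @param notch_frequency notch position in radians/sample, in (0, pi).
#' @param pole_radius pole radius `rho` of G(z), in (0, 1).
#' @param feedback feedback gain `alpha >= 0`.
#' @return object of class `feedback_notch` with fields `b`, `a`
#'   (closed-loop coefficients), `g_b`, `g_a` (the inner notch), and the
#'   design parameters.
#' @export
design_feedback_notch <- function(notch_frequency, pole_radius = 0.995,
                                  feedback = 3) {
  w <- notch_frequency
  if (!(w > 0 && w < pi)) {
    uv_stop("notch frequency must lie in (0, pi) radians/sample", "uwbvitals_param_error")
  }
  if (pole_radius >= 1) {
    uv_stop("pole radius must be < 1 for a stable notch", "uwbvitals_instability_error")
  }
  if (pole_radius <= 0 || feedback < 0) {
    uv_stop("need 0 < pole_radius < 1 and feedback >= 0", "uwbvitals_param_error")
  }
  g_b <- c(1, -2 * cos(w), 1)
  g_a <- c(1, -2 * pole_radius * cos(w), pole_radius^2)
  structure(list(b = (1 + feedback) * g_b,
                 a = g_a + feedback * g_b,
                 g_b = g_b, g_a = g_a,
                 notch_frequency = w, pole_radius = pole_radius,
                 feedback = feedback),
            class = "feedback_notch")
}

#' Frequency response of a rational filter
#'
#' @param filt a `feedback_notch` (or any list with `b`, `a`).
#' @param omega radian frequencies at which to evaluate.
#' @return complex response values.
#' @export
filter_response <- function(filt, omega) {
  ks <- seq_along(filt$b) - 1
  num <- vapply(omega, function(w) sum(filt$b * exp(-1i * w * ks)), complex(1))
  ka <- seq_along(filt$a) - 1
  den <- vapply(omega, function(w) sum(filt$a * exp(-1i * w * ka)), complex(1))
  num / den
}

#' Suppress respiratory harmonics with a feedback-notch cascade
#'
#' Applies one feedback notch per harmonic frequency, each zero-phase
#' (forward-backward), so every harmonic tone is excised while spectral
#' content away from the notches passes with negligible loss. An empty
#' harmonic list is a no-op.
#'
#' The record extension behind the zero-phase application is selectable.
#' `"model"` (default) extends by least-squares projection onto the
#' notch tones plus trend: an exactly linear operator that continues the
#' harmonic lines with no frequency error, giving the deepest possible
#' excision of the notched tones. `"ar"` extrapolates with a Burg
#' autoregressive model instead, which continues every strong line in
#' the record - including a cardiac tone lying within one
#' spectral-resolution cell of a notch, which the projection would
#' absorb and remove; the fit makes the operator signal-adaptive. The
#' full pipeline uses `"ar"` for exactly that reason.
#'
#' @param x a [signal_trace] or numeric vector.
#' @param rate sampling rate, Hz.
#' @param harmonics frequencies to notch, Hz.
#' @param pole_radius,feedback notch design parameters
#'   (see [design_feedback_notch()]).
#' @param extension record-extension scheme, `"ar"` or `"model"`.
#' @return filtered signal, same type as input.
#' @export
suppress_harmonics <- function(x, rate = NULL, harmonics = numeric(0),
                               pole_radius = 0.995, feedback = 3,
                               extension = c("model", "ar")) {
  s <- slow_signal(x, rate)
  extension <- match.arg(extension)
  if (!length(harmonics)) {
    message("empty harmonic list: returning the signal unchanged")
    return(x)
  }
  if (any(harmonics >= s$rate / 2) || any(harmonics <= 0)) {
    uv_stop("all notch frequencies must lie in (0, Nyquist)", "uwbvitals_param_error")
  }
  y <- s$samples
  omegas <- 2 * pi * harmonics / s$rate
  for (w in omegas) {
    nf <- design_feedback_notch(w, pole_radius, feedback)
    # every stage carries the whole harmonic set in its record extension
    y <- zero_phase_filter(nf$b, nf$a, y, tone_omega = omegas,
                           extension = extension)
  }
  rewrap_signal(y, x)
}

#' Estimate the heart rate from a harmonic-suppressed signal
#'
#' Argmax of the zero-padded magnitude spectrum inside the search band
#' (default 0.85-2 Hz, where resting heart rates concentrate).
#'
#' @param x a [signal_trace] or numeric vector.
#' @param rate sampling rate, Hz.
#' @param band search band, Hz.
#' @param pad zero-padding factor.
#' @return estimated heart rate in Hz.
#' @export
estimate_hr <- function(x, rate = NULL, band = c(0.85, 2.0), pad = 8) {
  estimate_rate(x, rate, band = band, pad = pad)
}
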