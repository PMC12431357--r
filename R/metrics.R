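#' Spectral peak signal-to-noise ratio on a magnitude spectrum
#'
#' `10 log10( S(kmax)^2 / mean of the other squared magnitudes )`, the
#' ratio of the squared spectral peak to the average squared magnitude
#' of the remaining in-band points (divisor `N - 1`). Ties for the peak
#' go to the lowest index. Invariant to global rescaling of the
#' spectrum.
#'
#' @param mag magnitude spectrum values, already restricted to the band
#'   of interest.
#' @return SNR in dB; `+Inf` (with a warning) when every non-peak point
#'   is zero.
#' @export
spectral_snr_db <- function(mag) {
  N <- length(mag)
  if (N < 2) uv_stop("need at least 2 in-band spectral points", "uwbvitals_param_error")
  kmax <- which.max(mag)
  rest <- mag[-kmax]
  if (all(rest == 0)) {
    uv_warn("degenerate spectrum: all non-peak points are zero", "uwbvitals_degenerate_warning")
    return(Inf)
  }
  10 * log10(mag[kmax]^2 / (sum(rest^2) / (N - 1)))
}

#' Signal-to-noise ratio of a slow-time signal in a band
#'
#' Computes the zero-padded (no window) magnitude spectrum of the
#' signal, restricts it to `band`, and applies [spectral_snr_db()].
#' Respiration and heartbeat spectra concentrate below 2 Hz, hence the
#' default band.
#'
#' @param x a [signal_trace] or numeric vector.
#' @param rate sampling rate, Hz.
#' @param band length-2 numeric band in Hz.
#' @param pad zero-padding factor.
#' @return SNR in dB.
#' @export
snr_db <- function(x, rate = NULL, band = c(0, 2), pad = 8) {
  s <- slow_signal(x, rate)
  sp <- spectrum_mag(s$samples, s$rate, pad)
  idx <- which(sp$freq >= band[1] & sp$freq <= band[2])
  spectral_snr_db(sp$mag[idx])
}

#' Rate estimation accuracy in percent
#'
#' `(1 - |estimated - reference| / reference) * 100`. May be negative
#' for gross errors; equals 100 when the estimate matches the reference.
#'
#' @param estimated estimated rate, Hz.
#' @param reference reference rate, Hz (> 0).
#' @return accuracy in percent.
#' @examples
#' rate_accuracy(0.3154, 0.3113)  # 98.68
#' @export
rate_accuracy <- function(estimated, reference) {
  if (!is.numeric(reference) || any(reference <= 0)) {
    uv_stop("reference rate must be positive", "uwbvitals_param_error")
  }
  (1 - abs(estimated - reference) / reference) * 100
}

#' Normality characterization of clutter samples
#'
#' Anderson-Darling normality test (case with estimated mean and
#' variance) plus a nonlinear least-squares fit of the Gaussian
#' probability density to the normalized amplitude histogram, reporting
#' the coefficient of determination of the fit.
#'
#' @param samples numeric amplitude series (>= 200 samples).
#' @param n_bins histogram bin count; default Sturges' rule.
#' @return object of class `clutter_fit_report`: `ad_statistic`,
#'   `p_value`, `mean`, `sd` (fitted), `r_squared`, `breaks`,
#'   `density`, `mids`.
#' @export
clutter_normality <- function(samples, n_bins = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 200) {
    uv_stop("need at least 200 samples", "uwbvitals_param_error")
  }
  if (stats::sd(samples) == 0) {
    uv_stop("constant samples: degenerate distribution", "uwbvitals_degenerate_error")
  }
  ad <- nortest::ad.test(samples)
  if (is.null(n_bins)) n_bins <- grDevices::nclass.Sturges(samples)
  breaks <- seq(min(samples), max(samples), length.out = n_bins + 1)
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  df <- data.frame(x = h$mids, d = h$density)
  start <- list(mu = mean(samples), sig = stats::sd(samples))
  # a histogram that already matches the start values exactly leaves the
  # NLS gradient singular; the moment fit then IS the least-squares fit
  fit <- tryCatch(
    minpack.lm::nlsLM(d ~ stats::dnorm(x, mu, sig), data = df, start = start,
                      lower = c(-Inf, .Machine$double.eps)),
    error = function(e) NULL)
  co <- if (is.null(fit)) unlist(start) else stats::coef(fit)
  res <- df$d - stats::dnorm(df$x, co[["mu"]], co[["sig"]])
  r2 <- 1 - sum(res^2) / sum((df$d - mean(df$d))^2)
  structure(list(ad_statistic = unname(ad$statistic),
                 p_value = unname(ad$p.value),
                 mean = co[["mu"]],
                 sd = co[["sig"]],
                 r_squared = r2,
                 breaks = breaks,
                 density = h$density,
                 mids = h$mids),
            class = "clutter_fit_report")
}

#' @export
print.clutter_fit_report <- function(x, ...) {
  cat("<clutter_fit_report>\n")
  cat(sprintf("  Anderson-Darling A = %.4g, p = %.4g\n", x$ad_statistic, x$p_value))
  cat(sprintf("  Gaussian fit: mean %.4g, sd %.4g, R^2 = %.4f (%d bins)\n",
              x$mean, x$sd, x$r_squared, length(x$mids)))
  invisible(x)
}
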