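#' Simulation configuration for synthetic radar cubes
#'
#' Bundles every generative parameter of the echo simulator: nominal
#' target range and chest-displacement model (sinusoidal respiration and
#' heartbeat components), the platform-motion model of the hovering
#' carrier, static reflectors, band-limited Gaussian vegetation clutter,
#' receiver noise and the pulse/geometry parameters of the radar.
#'
#' Defaults follow the radar parameters of the X4M200 class of IR-UWB
#' sensors (centre frequency 7.29 GHz, -10 dB bandwidth 1.4 GHz, bin
#' spacing 0.0514 m, frame rate 17 Hz) and conventional bio-radar chest
#' displacement amplitudes (respiration 5 mm, heartbeat 0.5 mm).
#'
#' @param d0 nominal target range, metres.
#' @param Ar,fr respiration displacement amplitude (m) and frequency (Hz).
#' @param Ah,fh heartbeat displacement amplitude (m) and frequency (Hz).
#' @param platform_motion `"none"`, or a list: `list(model = "sinusoid",
#'   amplitude =, frequency =)`, `list(model = "random_walk", step_std =)`,
#'   or `list(model = "trace", values =)`.
#' @param reflectors list of static scatterers, each
#'   `list(range =, amplitude =)`.
#' @param clutter `"none"` or `list(model = "gaussian", sigma =,
#'   band = c(0.1, 3.5), bins = NULL)`; `sigma` is the total complex
#'   standard deviation per affected bin (in echo-amplitude units) and
#'   `bins = NULL` means every bin.
#' @param noise_std receiver white-noise total complex std.
#' @param duration record length, seconds.
#' @param frame_rate slow-time frame rate, Hz.
#' @param bin_spacing fast-time bin spacing, metres.
#' @param n_bins number of fast-time bins.
#' @param center_frequency carrier frequency, Hz.
#' @param t0_offset range of bin 1, metres.
#' @param pulse_bandwidth -10 dB bandwidth of the Gaussian-envelope
#'   transmitted pulse, Hz.
#' @param seed integer RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(d0 = 2, Ar = 0.005, fr = 0.3113, Ah = 5e-4, fh = 1.25,
                       platform_motion = "none",
                       reflectors = list(),
                       clutter = "none",
                       noise_std = 0,
                       duration = 30, frame_rate = 17,
                       bin_spacing = 0.0514, n_bins = 120,
                       center_frequency = 7.29e9, t0_offset = 0,
                       pulse_bandwidth = 1.4e9, seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  cfg$platform_motion <- normalize_motion(platform_motion)
  cfg$clutter <- normalize_clutter(clutter)
  if (!(fr > 0 && fr < fh)) {
    uv_stop("respiration frequency fr must satisfy 0 < fr < fh", "uwbvitals_config_error")
  }
  if (Ar < 0 || Ah < 0 || noise_std < 0) {
    uv_stop("amplitudes must be non-negative", "uwbvitals_config_error")
  }
  if (duration * frame_rate < 2) {
    uv_stop("duration x frame_rate must give at least 2 frames", "uwbvitals_config_error")
  }
  cfg
}

normalize_motion <- function(m) {
  if (is.character(m)) m <- list(model = m)
  if (is.null(m$model)) uv_stop("platform_motion needs a 'model' field", "uwbvitals_config_error")
  if (!m$model %in% c("none", "sinusoid", "random_walk", "trace")) {
    uv_stop(sprintf("unknown platform motion model '%s'", m$model), "uwbvitals_config_error")
  }
  m
}

normalize_clutter <- function(cl) {
  if (is.character(cl)) cl <- list(model = cl)
  if (is.null(cl$model)) uv_stop("clutter needs a 'model' field", "uwbvitals_config_error")
  if (!cl$model %in% c("none", "gaussian")) {
    uv_stop(sprintf("unknown clutter model '%s'", cl$model), "uwbvitals_config_error")
  }
  if (cl$model == "gaussian") {
    if (is.null(cl$sigma)) cl$sigma <- 0.2
    if (is.null(cl$band)) cl$band <- c(0.1, 3.5)
    if (cl$sigma < 0) uv_stop("clutter sigma must be >= 0", "uwbvitals_config_error")
  }
  cl
}

#' Simulate platform displacement over slow time
#'
#' @param model platform motion specification (see [sim_config()]).
#' @param n_frames number of slow-time frames.
#' @param frame_rate frame rate in Hz.
#' @param seed RNG seed for stochastic models.
#' @return numeric vector of per-frame displacements in metres.
#' @examples
#' simulate_platform_motion(list(model = "sinusoid", amplitude = 0.05,
#'                               frequency = 0.1), 100, 17)
#' @export
simulate_platform_motion <- function(model, n_frames, frame_rate, seed = 1L) {
  model <- normalize_motion(model)
  if (n_frames < 1) uv_stop("n_frames must be >= 1", "uwbvitals_param_error")
  t <- (seq_len(n_frames) - 1) / frame_rate
  switch(model$model,
    none = rep(0, n_frames),
    sinusoid = {
      if (is.null(model$amplitude) || is.null(model$frequency)) {
        uv_stop("sinusoid motion needs 'amplitude' and 'frequency'", "uwbvitals_config_error")
      }
      model$amplitude * sin(2 * pi * model$frequency * t)
    },
    random_walk = {
      if (is.null(model$step_std)) {
        uv_stop("random_walk motion needs 'step_std'", "uwbvitals_config_error")
      }
      set.seed(seed)
      cumsum(stats::rnorm(n_frames, 0, model$step_std))
    },
    trace = {
      v <- as.numeric(model$values)
      if (length(v) != n_frames) {
        uv_stop("supplied motion trace length does not match n_frames", "uwbvitals_config_error")
      }
      v
    })
}

# Two-pass (zero-phase) band-pass used for clutter shaping; returns the
# filter and its white-noise amplitude gain so output can be normalized
# analytically rather than empirically.
clutter_filter <- function(band, frame_rate) {
  nyq <- frame_rate / 2
  if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2]) {
    uv_stop("clutter band must lie strictly inside (0, frame_rate/2)", "uwbvitals_config_error")
  }
  bf <- signal::butter(4, band / nyq, type = "pass")
  nfft <- 8192
  B <- stats::fft(c(bf$b, rep(0, nfft - length(bf$b))))
  A <- stats::fft(c(bf$a, rep(0, nfft - length(bf$a))))
  H2 <- Mod(B / A)^2            # single-pass power response
  list(b = bf$b, a = bf$a, gain = sqrt(mean(H2^2)))
}

#' Simulate band-limited Gaussian clutter
#'
#' White Gaussian noise filtered (zero-phase) to the configured band and
#' rescaled by the analytic filter gain so the output standard deviation
#' equals `sigma`. The marginal distribution stays Gaussian, emulating
#' wind-driven vegetation clutter whose spectrum overlaps the
#' respiration/heartbeat band.
#'
#' @param model `"none"` or `list(model = "gaussian", sigma =, band =)`.
#' @param n_frames number of slow-time samples.
#' @param frame_rate Hz.
#' @param seed RNG seed.
#' @return numeric clutter trace of length `n_frames`.
#' @export
simulate_clutter <- function(model, n_frames, frame_rate, seed = 1L) {
  model <- normalize_clutter(model)
  if (model$model == "none" || model$sigma == 0) return(rep(0, n_frames))
  cf <- clutter_filter(model$band, frame_rate)
  set.seed(seed)
  w <- stats::rnorm(n_frames)
  zero_phase_filter(cf$b, cf$a, w) * model$sigma / cf$gain
}

# Gaussian pulse envelope std in range (m), from the -10 dB bandwidth.
pulse_range_sigma <- function(bandwidth) {
  sigma_f <- bandwidth / (2 * sqrt(log(10)))
  sigma_t <- 1 / (2 * pi * sigma_f)
  C_LIGHT * sigma_t / 2
}

#' Simulate a radar cube with ground truth
#'
#' Builds a complex-baseband slow-time x fast-time matrix frame by frame:
#' the target echo is a Gaussian pulse envelope centred at the
#' instantaneous chest range `d(t) = d0 + Ar sin(2 pi fr t) +
#' Ah sin(2 pi fh t) + d_platform(t)` carrying the phase
#' `4 pi d(t) / lambda`; static reflector echoes are centred at their
#' range plus the platform displacement; band-limited Gaussian clutter
#' and white receiver noise are added per bin.
#'
#' @param config a [sim_config()].
#' @return a list of class `uwb_simulation` with elements `cube`
#'   (a [radar_cube]) and `truth` (time axis, true displacement and
#'   platform traces, true rates, target bin).
#' @export
simulate_cube <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nf <- as.integer(round(config$duration * config$frame_rate))
  nb <- config$n_bins
  t <- (seq_len(nf) - 1) / config$frame_rate
  base_seed <- as.integer(config$seed %% 2147483591L)

  duav <- simulate_platform_motion(config$platform_motion, nf,
                                   config$frame_rate, seed = base_seed + 1L)
  chest <- config$Ar * sin(2 * pi * config$fr * t) +
           config$Ah * sin(2 * pi * config$fh * t)
  d <- config$d0 + chest + duav

  r <- config$t0_offset + (seq_len(nb) - 1) * config$bin_spacing
  rmax <- config$t0_offset + nb * config$bin_spacing
  if (any(d < config$t0_offset) || any(d >= rmax)) {
    uv_stop("target range leaves the sampled range window", "uwbvitals_range_error")
  }
  lambda <- C_LIGHT / config$center_frequency
  sig_r <- pulse_range_sigma(config$pulse_bandwidth)

  envelope <- exp(-outer(d, r, function(dd, rr) (rr - dd)^2) / (2 * sig_r^2))
  data <- envelope * exp(1i * 4 * pi * d / lambda)

  for (refl in config$reflectors) {
    rng <- refl$range + duav
    if (any(rng < config$t0_offset) || any(rng >= rmax)) {
      uv_stop("reflector range leaves the sampled range window", "uwbvitals_range_error")
    }
    env_s <- exp(-outer(rng, r, function(dd, rr) (rr - dd)^2) / (2 * sig_r^2))
    data <- data + refl$amplitude * env_s * exp(1i * 4 * pi * rng / lambda)
  }

  if (config$clutter$model == "gaussian" && config$clutter$sigma > 0) {
    cl_bins <- config$clutter$bins
    if (is.null(cl_bins)) cl_bins <- seq_len(nb)
    cf <- clutter_filter(config$clutter$band, config$frame_rate)
    set.seed(base_seed + 2L)
    w <- matrix(stats::rnorm(nf * 2L * length(cl_bins)), nf)
    filt <- apply(w, 2, function(col) zero_phase_filter(cf$b, cf$a, col))
    scale <- config$clutter$sigma / (sqrt(2) * cf$gain)
    ncl <- length(cl_bins)
    data[, cl_bins] <- data[, cl_bins] +
      scale * (filt[, seq_len(ncl)] + 1i * filt[, ncl + seq_len(ncl)])
  }

  if (config$noise_std > 0) {
    set.seed(base_seed + 3L)
    data <- data + config$noise_std / sqrt(2) *
      (matrix(stats::rnorm(nf * nb), nf) + 1i * matrix(stats::rnorm(nf * nb), nf))
  }

  cube <- radar_cube(data, config$frame_rate, config$bin_spacing,
                     config$center_frequency, config$t0_offset)
  truth <- list(time = t,
                displacement = d,
                chest = chest,
                platform = duav,
                rr_hz = config$fr,
                hr_hz = config$fh,
                target_bin = as.integer(round((config$d0 - config$t0_offset) /
                                              config$bin_spacing)) + 1L)
  structure(list(cube = cube, truth = truth, config = config),
            class = "uwb_simulation")
}

#' @export
print.uwb_simulation <- function(x, ...) {
  cat("<uwb_simulation>\n")
  print(x$cube)
  cat(sprintf("  truth: RR %g Hz, HR %g Hz, target bin %d\n",
              x$truth$rr_hz, x$truth$hr_hz, x$truth$target_bin))
  invisible(x)
}
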