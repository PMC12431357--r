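# Shared fixtures: all synthetic, built in code.

FS <- 17                     # slow-time frame rate, Hz
TT <- function(n = 510) (seq_len(n) - 1) / FS

tone <- function(f, n = 510, amp = 1, phase = 0) amp * sin(2 * pi * f * TT(n) + phase)

# Small complex cube with a single static scatterer (for io/shape tests).
toy_cube <- function(nf = 24, nb = 16, complex = TRUE, seed = 1) {
  set.seed(seed)
  d <- matrix(rnorm(nf * nb), nf, nb)
  if (complex) d <- d + 1i * matrix(rnorm(nf * nb), nf, nb)
  radar_cube(d, frame_rate = FS, bin_spacing = 0.0514, center_frequency = 7.29e9)
}

# The grassland-like study scene: breathing target over a distributed
# static background, sinusoidal platform drift and Gaussian clutter.
scene_args <- function(...) {
  utils::modifyList(
    list(d0 = 2.0, fr = 0.3113, fh = 1.25,
         platform_motion = list(model = "sinusoid", amplitude = 0.15, frequency = 0.1),
         reflectors = list(list(range = 1.2, amplitude = 0.8),
                           list(range = 3.5, amplitude = 1.2),
                           list(range = 4.5, amplitude = 0.9),
                           list(range = 5.3, amplitude = 0.7)),
         clutter = list(model = "gaussian", sigma = 0.2),
         noise_std = 0.02),
    list(...))
}

# Channel-domain separation fixture: two deterministic sources observed
# through a well-conditioned random mixing with homogeneous band-limited
# Gaussian clutter at a given mean signal-to-clutter ratio (dB).
#   - chest waveform: 0.3 Hz with a mild 2nd harmonic (sinusoid-ish)
#   - platform drift: 0.09 Hz residual at 0.4 amplitude (what the
#     100-frame DC canceller leaves of unit drift)
mixed_channels <- function(seed, n = 510, snr_db = 5, drift_amp = 0.4) {
  set.seed(seed)
  resp <- tone(0.3, n) + 0.2 * tone(0.6, n, phase = 1)
  drift <- tone(0.09, n, phase = stats::runif(1, 0, 2 * pi))
  S <- rbind(resp / stats::sd(resp), drift_amp * drift / stats::sd(drift))
  A <- qr.Q(qr(matrix(stats::rnorm(10), 5, 2))) %*% diag(stats::runif(2, 0.8, 1.2))
  X <- A %*% S
  cl <- sapply(1:5, function(i) {
    simulate_clutter(list(model = "gaussian", sigma = 1), n, FS, seed = seed * 100 + i)
  })
  sigc <- sqrt(mean(apply(X, 1, stats::var)) / 10^(snr_db / 10))
  list(channels = channel_set(X + t(cl) * sigc, FS),
       resp = resp, drift = drift, mixing = A)
}

expect_uv_error <- function(expr, class) {
  expect_error(expr, class = class)
}

# Independent off-diagonal-mass oracle (kept out of the package on purpose).
off_mass_oracle <- function(mats, U) {
  sum(vapply(mats, function(M) {
    R <- t(U) %*% M %*% U
    sum(R^2) - sum(diag(R)^2)
  }, numeric(1)))
}
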