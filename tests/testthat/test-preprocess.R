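test_that("envelope alignment leaves identical frames untouched and is idempotent", {
  sim <- simulate_cube(sim_config(Ar = 0, Ah = 0, platform_motion = "none",
                                  clutter = "none", noise_std = 0, duration = 3))
  al <- envelope_align(sim$cube)
  expect_true(all(al$shifts == 0))
  expect_equal(al$aligned$data, sim$cube$data)

  drift <- simulate_cube(sim_config(
    d0 = 39 * 0.0514,
    platform_motion = list(model = "sinusoid", amplitude = 0.15, frequency = 0.1),
    clutter = "none", noise_std = 0, seed = 4))
  al1 <- envelope_align(drift$cube)
  al2 <- envelope_align(al1$aligned)
  expect_true(all(al2$shifts == 0))
})

test_that("alignment recovers injected integer shifts exactly", {
  base <- simulate_cube(sim_config(platform_motion = "none", clutter = "none",
                                   noise_std = 0, duration = 3))$cube$data[1, ]
  inj <- c(0L, 3L, -2L, 5L, 1L, 0L, -4L, 2L, 3L, -1L)
  nb <- length(base)
  dat <- t(vapply(inj, function(s) {
    out <- rep(0 + 0i, nb)
    j <- seq_len(nb) - s
    ok <- j >= 1 & j <= nb
    out[which(ok)] <- base[j[ok]]
    out
  }, complex(nb)))
  al <- envelope_align(radar_cube(dat, FS, 0.0514, 7.29e9))
  expect_identical(al$shifts, inj)
})

test_that("alignment of sinusoidal platform drift stabilizes the target bin", {
  sim <- simulate_cube(sim_config(
    d0 = 39 * 0.0514,     # bin-centred target, bin 40
    platform_motion = list(model = "sinusoid", amplitude = 0.15, frequency = 0.1),
    clutter = "none", noise_std = 0, seed = 4))
  before <- apply(Mod(sim$cube$data), 1, which.max)
  expect_gt(length(unique(before)), 2)   # migration spans >= 3 bins

  al <- envelope_align(sim$cube)
  after <- apply(Mod(al$aligned$data), 1, which.max)
  expect_equal(length(unique(after)), 1L)
  expect_equal(unique(after), 40L)
})

test_that("all-zero frames are skipped with the shift carried forward", {
  cube <- toy_cube(nf = 10)
  cube$data[4, ] <- 0 + 0i
  expect_warning(al <- envelope_align(cube), class = "uwbvitals_alignment_warning")
  expect_equal(al$shifts[4], al$shifts[3])
})

test_that("phase compensation recovers injected per-frame offsets", {
  sim <- simulate_cube(sim_config(Ar = 0, Ah = 0, platform_motion = "none",
                                  clutter = "none", noise_std = 0, duration = 6))
  cube <- sim$cube
  nf <- n_frames(cube)
  set.seed(8)
  phi <- c(rep(0, 10), stats::runif(nf - 10, -pi, pi))  # benchmark frames clean
  cube$data <- cube$data * exp(1i * phi)
  out <- phase_compensate(cube, Na = 10)
  rec <- attr(out, "phase_corrections")
  err <- Arg(exp(1i * (rec - phi)))
  expect_lt(max(abs(err)), 1e-9)

  # identical phases across frames: corrections all zero
  flat <- simulate_cube(sim_config(Ar = 0, Ah = 0, platform_motion = "none",
                                   clutter = "none", noise_std = 0, duration = 3))$cube
  expect_lt(max(abs(attr(phase_compensate(flat, Na = 5), "phase_corrections"))), 1e-12)
})

test_that("phase compensation rejects real cubes and benchmark matches plain mean", {
  expect_uv_error(phase_compensate(toy_cube(complex = FALSE)), "uwbvitals_type_error")

  # phase-coherent frames (common pattern, varying positive gain): the
  # progressive benchmark reduces to the plain frame mean and the
  # corrections against it vanish
  set.seed(14)
  pattern <- complex(real = rnorm(16), imaginary = rnorm(16))
  gains <- runif(12, 0.5, 1.5)
  cube <- radar_cube(outer(gains, pattern), FS, 0.0514, 7.29e9)
  out1 <- phase_compensate(cube, Na = 12, weights = rep(1, 12), mask_factor = 0)
  bench <- colMeans(cube$data)
  rot <- cube$data %*% Conj(bench)
  expect_lt(max(abs(attr(out1, "phase_corrections"))), 1e-12)
  expect_equal(attr(out1, "phase_corrections"), Arg(rot)[, 1], tolerance = 1e-12)
})

test_that("moving-average DC removal annihilates constants and preserves the passband", {
  cube <- toy_cube(nf = 120)
  cube$data[] <- 3 + 0i
  out <- remove_dc(cube, 100)
  expect_lt(max(Mod(out$data)), 1e-12)

  zero <- radar_cube(matrix(0, 120, 8), FS, 0.0514, 7.29e9)
  expect_true(all(remove_dc(zero)$data == 0))

  # constant + 1 Hz tone: residual matches the direct-subtraction oracle
  n <- 510
  x <- 5 + tone(1, n)
  oracle <- x - vapply(seq_len(n), function(i) {
    lo <- max(1, i - 49); hi <- min(n, i + 50)
    mean(x[lo:hi])
  }, numeric(1))
  cube2 <- radar_cube(cbind(x, x), FS, 0.0514, 7.29e9)
  got <- remove_dc(cube2, 100)$data[, 1]
  expect_equal(got, oracle, tolerance = 1e-10)
  # tone essentially untouched (1 Hz is far above the 0.17 Hz MA cutoff)
  expect_lt(sqrt(mean((got - tone(1, n))^2)) / sqrt(mean(tone(1, n)^2)), 0.1)

  expect_uv_error(remove_dc(toy_cube(nf = 10), window = 50), "uwbvitals_param_error")
  expect_uv_error(remove_dc(toy_cube(), window = 1), "uwbvitals_param_error")
})

test_that("interior window means vanish after DC removal", {
  x <- 5 + 0.4 * TT() + tone(1)     # offset + linear drift + passband tone
  cube <- radar_cube(cbind(x, x), FS, 0.0514, 7.29e9)
  out <- Re(remove_dc(cube, 100)$data[, 1])
  for (i in seq(100, 380, by = 40)) {
    expect_lt(abs(mean(out[i:(i + 99)])), 0.1 * stats::sd(out))
  }
})

test_that("target localization takes the max-energy bin with lowest-index ties", {
  d <- matrix(0, 60, 50)
  d[, 39] <- tone(0.3, 60)
  loc <- locate_target(radar_cube(d, FS, 0.0514, 7.29e9))
  expect_equal(loc$bin, 39L)

  d2 <- matrix(0, 60, 50)
  d2[, 10] <- tone(0.3, 60)
  d2[, 20] <- tone(0.3, 60)
  expect_equal(locate_target(radar_cube(d2, FS, 0.0514, 7.29e9))$bin, 10L)

  expect_uv_error(locate_target(radar_cube(matrix(0, 4, 4), FS, 0.05, 7e9)),
                  "uwbvitals_target_error")
})

test_that("localization finds the simulated target at its geometric bin", {
  sim <- simulate_cube(sim_config(d0 = 2.0, platform_motion = "none",
                                  clutter = "none", noise_std = 0, seed = 6))
  dc <- remove_dc(sim$cube, 100)
  expect_equal(locate_target(dc)$bin, round(2.0 / 0.0514) + 1L)  # 39 bins from range 0
})

test_that("localization matches ground truth at high SNR across seeds", {
  hits <- vapply(1:20, function(s) {
    sim <- simulate_cube(do.call(sim_config, c(
      scene_args(platform_motion = "none", clutter = list(model = "gaussian", sigma = 0.1)),
      list(seed = s))))
    dc <- remove_dc(sim$cube, 100)
    locate_target(dc)$bin == sim$truth$target_bin
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("channel extraction returns phase signals around the target bin", {
  sim <- simulate_cube(sim_config(platform_motion = "none", clutter = "none",
                                  noise_std = 0, duration = 6))
  ch <- extract_channels(sim$cube, 48, half_width = 2)
  expect_equal(ch$bin_labels, 46:50)
  expect_equal(nrow(ch$signals), 5L)
  expect_equal(ch$type, "phase")

  one <- extract_channels(sim$cube, 40, half_width = 0)
  expect_equal(nrow(one$signals), 1L)
  expect_equal(one$signals[1, ], phase_unwrap(Arg(sim$cube$data[, 40])))

  expect_warning(edge <- extract_channels(sim$cube, 1, half_width = 2),
                 class = "uwbvitals_edge_warning")
  expect_equal(nrow(edge$signals), 3L)
  expect_equal(edge$bin_labels, 1:3)
})

test_that("baseline removal preserves oscillations and removes drift", {
  x <- tone(0.3)
  for (m in c("beads", "als")) {
    y <- remove_baseline(x, m, rate = FS)
    expect_lt(sqrt(mean((y - x)^2)) / sqrt(mean(x^2)), 0.05)

    dr <- seq(0, 3, length.out = 510)
    yd <- remove_baseline(dr, m, rate = FS)
    expect_lt(sqrt(mean(yd^2)) / sqrt(mean(dr^2)), 0.05)
  }
  expect_equal(remove_baseline(rep(0, 510), "beads", rate = FS), rep(0, 510))

  # <= 1 dB loss at 0.3 Hz with default parameters
  y3 <- remove_baseline(x, "beads", rate = FS)
  expect_lt(abs(20 * log10(stats::sd(y3) / stats::sd(x))), 1)

  expect_uv_error(remove_baseline(tone(0.3, 20), rate = FS), "uwbvitals_param_error")
  expect_uv_error(remove_baseline(c(tone(0.3, 509), NaN), rate = FS),
                  "uwbvitals_data_error")
})

test_that("prominent clusters separate target from static background", {
  sim <- simulate_cube(do.call(sim_config, c(scene_args(clutter = "none", noise_std = 0),
                                             list(seed = 1))))
  cl <- prominent_clusters(sim$cube)
  expect_gte(length(cl), 2)
  lone <- simulate_cube(sim_config(platform_motion = "none", clutter = "none",
                                   noise_std = 0))
  expect_equal(length(prominent_clusters(lone$cube)), 1L)
})
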