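test_that("whitening yields identity covariance and an orthogonal factor for white input", {
  set.seed(1)
  x <- matrix(rnorm(4 * 4000), 4)
  wh <- whiten(channel_set(x, FS), 4)
  C <- tcrossprod(wh$z - rowMeans(wh$z)) / ncol(wh$z)
  expect_lt(max(abs(C - diag(4))), 1e-8)
  expect_equal(wh$noise_variance, 0)

  # m = a, noiseless mixing: V C V' = I to 1e-10
  set.seed(2)
  S <- rbind(tone(0.3, 2000), runif(2000, -1, 1))
  X <- matrix(rnorm(4), 2) %*% S
  wh2 <- whiten(channel_set(X, FS), 2)
  Cx <- tcrossprod(X - rowMeans(X)) / ncol(X)
  expect_lt(max(abs(wh2$whitening_matrix %*% Cx %*% t(wh2$whitening_matrix) - diag(2))),
            1e-10)
})

test_that("noise variance is estimated from the discarded eigenvalues", {
  est <- vapply(1:50, function(s) {
    set.seed(s)
    S <- rbind(runif(2000, -sqrt(3), sqrt(3)), tone(0.3, 2000) * sqrt(2))
    A <- matrix(rnorm(10), 5, 2)
    X <- A %*% S + 0.1 * matrix(rnorm(5 * 2000), 5)
    whiten(channel_set(X, FS), 2)$noise_variance
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.01) / 0.01, 0.2)
})

test_that("degenerate channel sets are rejected by name", {
  s <- tone(0.3, 200)
  rank1 <- channel_set(rbind(s, s, s), FS, bin_labels = 38:40)
  err <- tryCatch(whiten(rank1, 3), error = function(e) e)
  expect_s3_class(err, "uwbvitals_degenerate_error")
  expect_match(conditionMessage(err), "bins")
  expect_uv_error(jade_separate(rank1, n_sources = 2), "uwbvitals_degenerate_error")
})

test_that("fourth-order cumulants annihilate Gaussian input", {
  set.seed(5)
  z <- matrix(rnorm(3 * 20000), 3)
  Q <- cumulant_matrices(whiten(channel_set(z, FS), 3))
  expect_equal(length(Q), 6L)          # m(m+1)/2 basis matrices
  expect_lt(max(abs(unlist(Q))), 0.12) # O(n^-1/2) sampling error at n = 2e4
})

test_that("the single-source cumulant equals the excess kurtosis", {
  set.seed(6)
  s <- runif(5000, -sqrt(3), sqrt(3))          # uniform: kurtosis -1.2
  z <- rbind((s - mean(s)) / stats::sd(s) * sqrt(4999 / 5000))
  # brute-force moment oracle for cum(s,s,s,s) on the same standardized data
  kappa <- mean(z^4) - 3 * mean(z^2)^2
  Q <- cumulant_matrices(z)
  expect_equal(Q[[1]][1, 1], kappa, tolerance = 1e-8)
  expect_lt(abs(kappa - (-1.2)), 0.1)
})

test_that("cumulants of an exact normal quantile grid vanish", {
  g <- qnorm((seq_len(20000) - 0.5) / 20000)
  z <- rbind((g - mean(g)) / (stats::sd(g) * sqrt(19999 / 20000)))
  Q <- cumulant_matrices(z)
  expect_lt(abs(Q[[1]][1, 1]), 0.01)
})

test_that("non-whitened input is rejected by the cumulant contract", {
  set.seed(7)
  z <- matrix(rnorm(2 * 1000), 2) * c(2, 0.5)
  expect_uv_error(cumulant_matrices(z), "uwbvitals_contract_error")
})

test_that("joint diagonalization inverts a known rotation", {
  set.seed(11)
  for (m in c(2, 4)) {
    G <- qr.Q(qr(matrix(rnorm(m * m), m)))
    mats <- lapply(1:3, function(k) {
      D <- diag(stats::runif(m, -2, 2))
      G %*% D %*% t(G)
    })
    U <- joint_diagonalize(mats)
    expect_lt(off_mass_oracle(mats, U), 1e-10)
    # U equals G up to column sign/permutation
    M <- abs(t(U) %*% G)
    expect_equal(sort(apply(M, 1, max)), rep(1, m), tolerance = 1e-7)
  }
})

test_that("joint diagonalization of diagonal and single matrices is trivial", {
  mats <- list(diag(c(3, 1, -2)), diag(c(0.5, -1, 2)))
  U <- joint_diagonalize(mats)
  expect_equal(sort(apply(abs(U), 1, max)), rep(1, 3), tolerance = 1e-10)

  set.seed(12)
  M <- crossprod(matrix(rnorm(16), 4))
  U1 <- joint_diagonalize(list(M))
  R <- t(U1) %*% M %*% U1
  expect_lt(sum(R^2) - sum(diag(R)^2), 1e-10)
  expect_equal(sort(diag(R)), sort(eigen(M)$values), tolerance = 1e-8)

  expect_uv_error(joint_diagonalize(list(matrix(1:4, 2))), "uwbvitals_contract_error")
})

test_that("JADE recovers a single source through duplicate channels", {
  s <- tone(0.3) + 0.3 * tone(0.6, phase = 0.5)
  sep <- jade_separate(channel_set(rbind(s, s), FS), n_sources = 1)
  expect_gt(abs(cor(sep$components[1, ], s)), 0.999)
  expect_equal(sep$selected_respiratory, 1L)
})

test_that("JADE separates respiration from drift under 5 dB clutter", {
  ok <- 0L
  for (s in 1:20) {
    fx <- mixed_channels(s)
    sep <- jade_separate(fx$channels, n_sources = 2)
    if (max(abs(cor(t(sep$components), fx$resp))) >= 0.95) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})

test_that("separation quality is invariant to channel order and positive rescaling", {
  fx <- mixed_channels(3)
  base <- jade_separate(fx$channels, n_sources = 2)
  c0 <- max(abs(cor(t(base$components), fx$resp)))

  perm <- fx$channels$signals[c(4, 1, 5, 2, 3), ]
  c1 <- max(abs(cor(t(jade_separate(channel_set(perm, FS), 2)$components), fx$resp)))
  expect_equal(c1, c0, tolerance = 1e-6)

  # rescaling invariance is exact in the square noiseless case, where the
  # scaling is absorbed into the mixing matrix (with retained noise the
  # principal subspace itself is scale-dependent)
  set.seed(31)
  S <- rbind(tone(0.3) + 0.2 * tone(0.6, phase = 1),
             sign(tone(0.07, phase = 0.3)))
  X <- matrix(c(1.2, -0.4, 0.3, 0.9), 2) %*% S
  cs <- function(x) max(abs(cor(t(jade_separate(channel_set(x, FS), 2)$components), S[1, ])))
  expect_equal(cs(X * c(3, 0.25)), cs(X), tolerance = 1e-6)
  expect_gt(cs(X), 0.999)
})

test_that("recovery degrades monotonically with the noise level", {
  sigmas <- c(0, 0.1, 0.5, 1)
  mean_cor <- vapply(sigmas, function(sg) {
    mean(vapply(1:12, function(s) {
      set.seed(s)
      src <- rbind(tone(0.3) + 0.2 * tone(0.6, phase = 1),
                   sign(tone(0.07, phase = runif(1, 0, 2 * pi))))  # two non-Gaussian sources
      src <- src / apply(src, 1, stats::sd)
      A <- qr.Q(qr(matrix(rnorm(10), 5, 2)))
      X <- A %*% src + sg * matrix(rnorm(5 * 510), 5)
      sep <- jade_separate(channel_set(X, FS), n_sources = 2)
      max(abs(cor(t(sep$components), src[1, ])))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_cor) <= 0.02))
})

test_that("components are ordered and sign-normalized, and the unitary factor is orthogonal", {
  fx <- mixed_channels(9)
  sep <- jade_separate(fx$channels, n_sources = 2)
  expect_lt(max(abs(crossprod(sep$unitary_estimate) - diag(2))), 1e-8)
  for (i in 1:2) {
    y <- sep$components[i, ]
    expect_gt(y[which.max(abs(y))], 0)
  }
})

test_that("respiratory selection picks the slow tone and flags hopeless sets", {
  comps <- rbind(tone(0.3), tone(1.2))
  fake <- structure(list(components = comps, rate = FS,
                         whitening_matrix = diag(2), noise_variance = 0,
                         unitary_estimate = diag(2), eigenvalues = c(1, 1),
                         selected_respiratory = NA_integer_),
                    class = "separation_result")
  sel <- select_respiratory(fake)
  expect_equal(sel$index, 1L)
  expect_false(sel$flagged)

  set.seed(4)
  noise <- matrix(rnorm(2 * 510), 2)   # white: band ratio ~ (0.5/8.5) < 0.2
  fake$components <- noise
  expect_warning(sel2 <- select_respiratory(fake),
                 class = "uwbvitals_no_respiration_warning")
  expect_true(sel2$flagged)

  fake$components <- rbind(tone(0.25))
  expect_equal(select_respiratory(fake)$index, 1L)
})
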