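#' Whiten a channel set (with noise-variance correction)
#'
#' Centres each channel and applies a linear transform so the output
#' rows have identity covariance, reducing the unknown mixing matrix to
#' an orthogonal factor. With `n_sources < n_channels` the noise
#' variance is estimated as the mean of the discarded (smallest)
#' covariance eigenvalues and subtracted from the leading eigenvalues
#' before scaling, so the signal subspace is scaled by its noise-free
#' power; the rows are then renormalized to exactly unit sample variance.
#'
#' @param channels a [channel_set] or channels x frames matrix.
#' @param n_sources number of sources `m` to retain (default: all
#'   channels).
#' @return object of class `whitening`: `z` (m x n whitened data),
#'   `whitening_matrix` (m x a), `noise_variance`, `eigenvalues`,
#'   `center` (row means), `rate`.
#' @export
whiten <- function(channels, n_sources = NULL) {
  x <- if (inherits(channels, "channel_set")) channels$signals else as.matrix(channels)
  rate <- if (inherits(channels, "channel_set")) channels$rate else NA_real_
  labels <- if (inherits(channels, "channel_set")) channels$bin_labels else seq_len(nrow(x))
  a <- nrow(x)
  n <- ncol(x)
  if (a < 2) uv_stop("need at least 2 channels for separation", "uwbvitals_param_error")
  if (n <= a) uv_stop("need more frames than channels", "uwbvitals_param_error")
  m <- if (is.null(n_sources)) a else as.integer(n_sources)
  if (m < 1 || m > a) uv_stop("n_sources must be in 1..n_channels", "uwbvitals_param_error")

  center <- rowMeans(x)
  xc <- x - center
  C <- tcrossprod(xc) / n
  eg <- eigen(C, symmetric = TRUE)
  ev <- eg$values
  if (ev[m] <= max(ev) * 1e-10) {
    bad <- labels[seq.int(m, a)]
    uv_stop(sprintf("channel covariance has rank < %d (degenerate channels near bins %s)",
                    m, paste(bad, collapse = ",")), "uwbvitals_degenerate_error")
  }
  sigma2 <- if (m < a) mean(ev[(m + 1):a]) else 0
  scl <- ev[seq_len(m)] - sigma2
  if (any(scl <= 0)) {
    uv_stop("noise-corrected eigenvalues are not positive; reduce n_sources",
            "uwbvitals_degenerate_error")
  }
  V <- diag(1 / sqrt(scl), m) %*% t(eg$vectors[, seq_len(m), drop = FALSE])
  z <- V %*% xc
  # exact unit row variance (the noise correction inflates it slightly)
  rv <- sqrt(rowSums(z^2) / n)
  V <- V / rv
  z <- z / rv
  structure(list(z = z, whitening_matrix = V, noise_variance = sigma2,
                 eigenvalues = ev, center = center, rate = rate,
                 bin_labels = labels),
            class = "whitening")
}

# Symmetric basis of m x m matrices: e_p e_p' and (e_p e_q' + e_q e_p')/sqrt(2).
cumulant_basis <- function(m) {
  out <- list()
  for (p in seq_len(m)) {
    M <- matrix(0, m, m)
    M[p, p] <- 1
    out[[length(out) + 1L]] <- M
  }
  if (m > 1) {
    for (p in seq_len(m - 1)) {
      for (q in (p + 1):m) {
        M <- matrix(0, m, m)
        M[p, q] <- M[q, p] <- 1 / sqrt(2)
        out[[length(out) + 1L]] <- M
      }
    }
  }
  out
}

#' Fourth-order cumulant matrices of whitened data
#'
#' For each matrix `M` of the symmetric basis, computes the sample
#' cumulant matrix `Q(M)_ij = sum_kl cum(z_i, z_j, z_k, z_l) M_kl` with
#' `cum(a,b,c,d) = E[abcd] - E[ab]E[cd] - E[ac]E[bd] - E[ad]E[bc]`.
#' Cumulants of Gaussian processes vanish, which is what lets the
#' subsequent diagonalization suppress Gaussian clutter.
#'
#' @param whitened a `whitening` object or m x n matrix with (near)
#'   identity covariance.
#' @param cov_tol largest allowed deviation of the sample covariance
#'   from identity before the input is rejected.
#' @return list of m(m+1)/2 symmetric m x m matrices.
#' @export
cumulant_matrices <- function(whitened, cov_tol = 1e-3) {
  z <- if (inherits(whitened, "whitening")) whitened$z else as.matrix(whitened)
  m <- nrow(z)
  n <- ncol(z)
  if (n < 10 * m^2) {
    uv_stop(sprintf("need n >= 10 m^2 samples (have n = %d, m = %d)", n, m),
            "uwbvitals_param_error")
  }
  zc <- z - rowMeans(z)
  C <- tcrossprod(zc) / n
  if (max(abs(C - diag(m))) > cov_tol) {
    uv_stop("input is not whitened (covariance deviates from identity)",
            "uwbvitals_contract_error")
  }
  lapply(cumulant_basis(m), function(M) {
    q <- colSums((M %*% zc) * zc)
    S4 <- (zc * rep(q, each = m)) %*% t(zc) / n
    Q <- S4 - C * sum(C * M) - 2 * (C %*% M %*% C)
    (Q + t(Q)) / 2
  })
}

#' Joint approximate diagonalization of symmetric matrices
#'
#' Jacobi/Givens sweeps (Cardoso-Souloumiac) minimizing the summed
#' squared off-diagonal mass of the rotated matrix set. Sweeps stop when
#' no rotation angle exceeds `tol` or after `max_sweeps`.
#'
#' @param matrices list of symmetric m x m matrices.
#' @param tol rotation-sine threshold for convergence.
#' @param max_sweeps sweep limit.
#' @return orthogonal m x m matrix `U` such that `t(U) %*% Q %*% U` is
#'   jointly (approximately) diagonal; attribute `"sweeps"` records the
#'   number of sweeps used.
#' @export
joint_diagonalize <- function(matrices, tol = 1e-8, max_sweeps = 100) {
  if (!length(matrices)) uv_stop("empty matrix set", "uwbvitals_param_error")
  m <- nrow(matrices[[1]])
  for (M in matrices) {
    if (!is.matrix(M) || nrow(M) != m || ncol(M) != m ||
        max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M)))) {
      uv_stop("all matrices must be symmetric and of equal size", "uwbvitals_contract_error")
    }
  }
  K <- length(matrices)
  A <- array(unlist(matrices), dim = c(m, m, K))
  V <- diag(m)
  if (m == 1) return(structure(V, sweeps = 0L))
  sweeps <- 0L
  repeat {
    rotated <- FALSE
    sweeps <- sweeps + 1L
    for (p in 1:(m - 1)) {
      for (q in (p + 1):m) {
        h1 <- A[p, p, ] - A[q, q, ]
        h2 <- A[p, q, ] + A[q, p, ]
        ton <- sum(h1^2) - sum(h2^2)
        toff <- 2 * sum(h1 * h2)
        theta <- 0.5 * atan2(toff, ton + sqrt(ton^2 + toff^2))
        cs <- cos(theta)
        sn <- sin(theta)
        if (abs(sn) > tol) {
          rotated <- TRUE
          colp <- A[, p, ]
          colq <- A[, q, ]
          A[, p, ] <- cs * colp + sn * colq
          A[, q, ] <- cs * colq - sn * colp
          rowp <- A[p, , ]
          rowq <- A[q, , ]
          A[p, , ] <- cs * rowp + sn * rowq
          A[q, , ] <- cs * rowq - sn * rowp
          vp <- V[, p]
          V[, p] <- cs * vp + sn * V[, q]
          V[, q] <- cs * V[, q] - sn * vp
        }
      }
    }
    if (!rotated || sweeps >= max_sweeps) break
  }
  structure(V, sweeps = sweeps)
}

# Summed squared off-diagonal mass of {t(U) Q U}.
off_diag_mass <- function(matrices, U = NULL) {
  sum(vapply(matrices, function(M) {
    R <- if (is.null(U)) M else t(U) %*% M %*% U
    sum(R^2) - sum(diag(R)^2)
  }, numeric(1)))
}

#' JADE blind source separation
#'
#' Runs the full JADE recipe on a slow-time channel set: centring and
#' whitening (with noise-variance correction when `n_sources` is below
#' the channel count), fourth-order cumulant matrices, joint approximate
#' diagonalization, and source recovery `Y = t(U) V X`. Components are
#' ordered by descending in-band (0.05-3.5 Hz by default) spectral
#' energy and sign-normalized so each component's largest-magnitude peak
#' is positive.
#'
#' Recovered sources carry the usual blind-separation ambiguity: scale
#' and order are arbitrary, so comparisons should use absolute
#' correlation after matching.
#'
#' @param channels a [channel_set] or channels x frames matrix.
#' @param n_sources number of sources (default: number of channels).
#' @param rate sampling rate, Hz; taken from the channel set when given.
#' @param energy_band Hz band used to order components.
#' @param resp_band Hz band used to pre-select the respiratory
#'   component (see [select_respiratory()]).
#' @return object of class `separation_result`: `components` (m x n),
#'   `whitening_matrix`, `noise_variance`, `unitary_estimate`,
#'   `eigenvalues`, `rate`, `selected_respiratory`.
#' @export
jade_separate <- function(channels, n_sources = NULL, rate = NULL,
                          energy_band = c(0.05, 3.5), resp_band = c(0.1, 0.6)) {
  wh <- whiten(channels, n_sources)
  if (!is.na(wh$rate)) rate <- wh$rate
  if (is.null(rate)) uv_stop("sampling rate unknown; supply `rate`", "uwbvitals_param_error")
  Q <- cumulant_matrices(wh)
  U <- joint_diagonalize(Q)
  Y <- t(U) %*% wh$z
  m <- nrow(Y)

  inband <- apply(Y, 1, function(y) {
    sp <- spectrum_mag(y - mean(y), rate, pad = 4)
    idx <- sp$freq >= energy_band[1] & sp$freq <= energy_band[2]
    sum(sp$mag[idx]^2)
  })
  ord <- order(inband, decreasing = TRUE)
  Y <- Y[ord, , drop = FALSE]
  U <- U[, ord, drop = FALSE]
  sgn <- apply(Y, 1, function(y) sign(y[which.max(abs(y))]))
  sgn[sgn == 0] <- 1
  Y <- Y * sgn
  U <- U * rep(sgn, each = nrow(U))

  res <- structure(list(components = Y,
                        whitening_matrix = wh$whitening_matrix,
                        noise_variance = wh$noise_variance,
                        unitary_estimate = U,
                        eigenvalues = wh$eigenvalues,
                        rate = rate,
                        selected_respiratory = NA_integer_),
                   class = "separation_result")
  validate_separation(res, wh$z)
  sel <- suppressWarnings(select_respiratory(res, band = resp_band))
  res$selected_respiratory <- sel$index
  res
}

validate_separation <- function(res, z) {
  Cz <- tcrossprod(z - rowMeans(z)) / ncol(z)
  if (max(abs(Cz - diag(nrow(z)))) > 1e-8) {
    uv_stop("whitened data covariance deviates from identity", "uwbvitals_contract_error")
  }
  U <- res$unitary_estimate
  if (max(abs(crossprod(U) - diag(ncol(U)))) > 1e-8) {
    uv_stop("estimated unitary matrix is not orthogonal", "uwbvitals_contract_error")
  }
  invisible(res)
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf("<separation_result> %d components x %d frames @ %g Hz\n",
              nrow(x$components), ncol(x$components), x$rate))
  cat(sprintf("  noise variance %.4g | respiratory component %s\n",
              x$noise_variance,
              ifelse(is.na(x$selected_respiratory), "?", x$selected_respiratory)))
  invisible(x)
}

#' Select the respiratory component of a separation
#'
#' Scores every recovered component by the fraction of its spectral
#' power (0 to Nyquist) falling in the respiration band and returns the
#' maximizer (ties to the lowest index). If no component concentrates
#' more than 20% of its power in the band, a warning is raised and the
#' best candidate is returned flagged.
#'
#' @param result a `separation_result`.
#' @param band respiration band in Hz.
#' @return list with `index`, `waveform` (a [signal_trace]), `ratio`,
#'   `flagged`.
#' @export
select_respiratory <- function(result, band = c(0.1, 0.6)) {
  stopifnot(inherits(result, "separation_result"))
  Y <- result$components
  if (nrow(Y) < 1) uv_stop("no components", "uwbvitals_param_error")
  ratios <- apply(Y, 1, function(y) {
    sp <- spectrum_mag(y - mean(y), result$rate, pad = 4)
    tot <- sum(sp$mag^2)
    if (tot == 0) return(0)
    idx <- sp$freq >= band[1] & sp$freq <= band[2]
    sum(sp$mag[idx]^2) / tot
  })
  idx <- which.max(ratios)
  flagged <- ratios[idx] <= 0.2
  if (flagged) {
    uv_warn(sprintf("no component has > 20%% of its power in %.2g-%.2g Hz; returning best candidate",
                    band[1], band[2]), "uwbvitals_no_respiration_warning")
  }
  list(index = idx,
       waveform = signal_trace(Y[idx, ], result$rate, "respiration (JADE)"),
       ratio = ratios[idx],
       flagged = flagged)
}
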