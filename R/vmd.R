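#' Variational mode decomposition
#'
#' Decomposes a signal into `K` narrowband AM-FM intrinsic mode functions
#' (IMFs) by the standard alternating-direction (ADMM) scheme: each mode is a
#' Wiener-filtered slice of the spectrum around its center frequency, and
#' center frequencies are updated to the spectral centroid of their mode
#' until the relative change falls below `tol`. The signal is mirrored at
#' both ends before the spectral iteration (the usual boundary treatment)
#' and the middle half kept afterwards. Deterministic: center frequencies
#' start uniformly spaced over the positive band.
#'
#' @param y a [sampled_signal()] or numeric vector with `ts`.
#' @param K number of modes (9 works well for vital-sign signals, covering
#'   breathing, heartbeat, their harmonics and noise).
#' @param alpha bandwidth penalty (larger = narrower modes).
#' @param tau dual-ascent step; 0 (default) tolerates noise.
#' @param tol convergence threshold on the relative mode update.
#' @param max_iter iteration cap; non-convergence sets `converged = FALSE`
#'   with a warning.
#' @param ts sampling interval when `y` is a plain vector.
#' @return An object of class `"imf_set"`: list with `imfs` (matrix, one
#'   column per mode, ordered by increasing center frequency),
#'   `center_freq` (Hz), `ts`, `residual` (input minus mode sum),
#'   `rel_residual`, `converged`. Instantaneous tracks are added by
#'   [hilbert_huang()].
#' @export
vmd_decompose <- function(y, K = 9, alpha = 2000, tau = 0, tol = 1e-7,
                          max_iter = 500, ts = NULL) {
  y <- as_sampled_signal(y, ts = ts)
  x <- y$samples
  n <- length(x)
  if (K < 1) stop("'K' must be at least 1")
  h <- n %/% 2
  xm <- c(rev(x[1:h]), x, rev(x[(h + 1):n]))      # mirror both ends
  n2 <- length(xm)                                 # == 2 * n for even n
  freqs <- (seq_len(n2) - 1) / n2                  # cyclic frequency grid
  freqs <- ifelse(freqs >= 0.5, freqs - 1, freqs)  # (-0.5, 0.5)
  xhat <- stats::fft(xm)
  xhat_plus <- xhat
  xhat_plus[freqs < 0] <- 0
  u_hat <- matrix(0 + 0i, n2, K)
  omega <- (0.5 / K) * (seq_len(K) - 1)            # uniform init
  lambda_hat <- complex(n2)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    u_prev <- u_hat
    for (k in seq_len(K)) {
      others <- rowSums(u_hat[, -k, drop = FALSE])
      u_hat[, k] <- (xhat_plus - others - lambda_hat / 2) /
        (1 + alpha * (freqs - omega[k])^2)
      pw <- Mod(u_hat[freqs >= 0, k])^2
      if (sum(pw) > 0)
        omega[k] <- sum(freqs[freqs >= 0] * pw) / sum(pw)
    }
    if (tau != 0)
      lambda_hat <- lambda_hat + tau * (rowSums(u_hat) - xhat_plus)
    dn <- sum(Mod(u_hat - u_prev)^2) / max(sum(Mod(u_prev)^2), 1e-300)
    if (it > 1 && dn < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("VMD did not converge within 'max_iter' iterations")
  # back to time domain: hermitian completion, inverse FFT, un-mirror
  imfs <- matrix(0, n, K)
  half <- if (n2 %% 2 == 0) n2 %/% 2 + 1L else (n2 + 1L) %/% 2
  for (k in seq_len(K)) {
    full <- u_hat[, k]
    if (half + 1L <= n2) {
      ineg <- (half + 1L):n2
      full[ineg] <- Conj(u_hat[n2 - ineg + 2L, k])
    }
    if (n2 %% 2 == 0) full[half] <- Re(u_hat[half, k])  # Nyquist bin
    um <- Re(stats::fft(full, inverse = TRUE)) / n2
    imfs[, k] <- um[(h + 1):(h + n)]
  }
  ord <- order(omega)
  imfs <- imfs[, ord, drop = FALSE]
  omega <- omega[ord]
  resid <- x - rowSums(imfs)
  structure(list(imfs = imfs, center_freq = omega / y$ts, ts = y$ts,
                 residual = resid,
                 rel_residual = rms(resid) / max(rms(x), 1e-300),
                 converged = converged),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("imf_set: %d modes, %d samples at %g Hz, relative residual %.3g\n",
              ncol(x$imfs), nrow(x$imfs), 1 / x$ts, x$rel_residual))
  if (!is.null(x$mean_freq))
    print(data.frame(imf = seq_along(x$mean_freq),
                     mean_freq_Hz = round(x$mean_freq, 3),
                     mean_energy = signif(x$mean_energy, 3)),
          row.names = FALSE)
  else
    cat("center frequencies [Hz]:", paste(round(x$center_freq, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Hilbert-Huang spectral tracks for an IMF set
#'
#' Computes each mode's analytic signal, giving the instantaneous envelope
#' and instantaneous frequency (phase derivative, clamped at zero since IMF
#' phases are non-decreasing), plus the amplitude-weighted mean frequency
#' and mean energy (mean squared envelope) used for mode selection.
#'
#' @param imfset an [vmd_decompose()] result.
#' @return the `imf_set` with `inst_freq`, `inst_amp` (matrices), `mean_freq`
#'   (Hz, `NA` for a zero mode) and `mean_energy` filled.
#' @export
hilbert_huang <- function(imfset) {
  stopifnot(inherits(imfset, "imf_set"))
  n <- nrow(imfset$imfs)
  K <- ncol(imfset$imfs)
  inst_freq <- inst_amp <- matrix(0, n, K)
  mean_freq <- numeric(K)
  mean_energy <- numeric(K)
  for (k in seq_len(K)) {
    u <- imfset$imfs[, k]
    a <- analytic_signal(u)
    env <- Mod(a)
    ph <- unwrap_phase(Arg(a))
    f <- c(diff(ph), ph[n] - ph[n - 1]) / (2 * pi * imfset$ts)
    f <- pmax(f, 0)
    inst_amp[, k] <- env
    inst_freq[, k] <- f
    mean_energy[k] <- mean(env^2)
    mean_freq[k] <- if (mean_energy[k] > 1e-300)
      sum(f * env) / sum(env) else NA_real_
  }
  imfset$inst_freq <- inst_freq
  imfset$inst_amp <- inst_amp
  imfset$mean_freq <- mean_freq
  imfset$mean_energy <- mean_energy
  imfset
}

# analytic signal via the frequency-domain Hilbert mask
analytic_signal <- function(u) {
  n <- length(u)
  U <- stats::fft(u)
  hmask <- numeric(n)
  if (n %% 2 == 0) {
    hmask[c(1, n / 2 + 1)] <- 1
    hmask[2:(n / 2)] <- 2
  } else {
    hmask[1] <- 1
    hmask[2:((n + 1) / 2)] <- 2
  }
  stats::fft(U * hmask, inverse = TRUE) / n
}

#' Select breathing and heartbeat IMFs
#'
#' Mirrors the pole-domain post-processing in the mode domain: the IMF with
#' the highest energy whose mean frequency lies in the breathing band is the
#' respiration mode; IMFs near its harmonics are excluded. Among the rest,
#' the strongest IMF with mean frequency in the heart band is the heartbeat,
#' with a harmonic-presence disambiguation (a candidate lacking any harmonic
#' IMF is skipped for the next-strongest that has one). The artery pulsation
#' is the sum of the heartbeat IMF and its harmonic IMFs (first
#' `n_harmonics`).
#'
#' @param imfset an [vmd_decompose()] result; [hilbert_huang()] is applied if
#'   tracks are missing.
#' @param breathing_band,heart_band bands in Hz.
#' @param n_harmonics harmonics searched.
#' @param harmonic_check enable the disambiguation rule.
#' @param abs_tol,rel_tol harmonic matching tolerance (same rule as the pole
#'   pipeline).
#' @return list with `f_b`, `f_h` (Hz or `NA`), `breathing_imf`,
#'   `heartbeat_imfs` (indices), `respiration`, `pulsation`
#'   ([sampled_signal()]s).
#' @export
select_vital_imfs <- function(imfset, breathing_band = c(0.1, 0.4),
                              heart_band = c(0.8, 2), n_harmonics = 4,
                              harmonic_check = TRUE,
                              abs_tol = 0.05, rel_tol = 0.04) {
  stopifnot(inherits(imfset, "imf_set"))
  if (is.null(imfset$mean_freq)) imfset <- hilbert_huang(imfset)
  mf <- imfset$mean_freq
  en <- imfset$mean_energy
  n <- nrow(imfset$imfs)
  zero_sig <- sampled_signal(rep(0, n), ts = imfset$ts)
  # breathing mode
  bc <- which(!is.na(mf) & mf >= breathing_band[1] & mf <= breathing_band[2])
  f_b <- NA_real_; b_idx <- integer(0); b_harm <- integer(0)
  if (length(bc)) {
    b_idx <- bc[which.max(en[bc])]
    f_b <- mf[b_idx]
    for (k in 2:n_harmonics)
      b_harm <- union(b_harm,
                      which(!is.na(mf) & abs(mf - k * f_b) <=
                              harmonic_tol(k, f_b, abs_tol, rel_tol)))
    b_harm <- setdiff(b_harm, b_idx)
  }
  avail <- setdiff(seq_along(mf), c(b_idx, b_harm))
  hc <- avail[!is.na(mf[avail]) & mf[avail] >= heart_band[1] & mf[avail] <= heart_band[2]]
  f_h <- NA_real_; h_idx <- integer(0); h_harm <- integer(0)
  if (length(hc)) {
    ord <- hc[order(-en[hc], mf[hc])]
    pick <- ord[1]
    if (harmonic_check) {
      for (i in ord) {
        has <- FALSE
        for (k in 2:n_harmonics) {
          hit <- setdiff(which(!is.na(mf) & abs(mf - k * mf[i]) <=
                                 harmonic_tol(k, mf[i], abs_tol, rel_tol)),
                         c(i, b_idx, b_harm))
          if (length(hit)) { has <- TRUE; break }
        }
        if (has) { pick <- i; break }
      }
    }
    h_idx <- pick
    f_h <- mf[h_idx]
    for (k in 2:n_harmonics)
      h_harm <- union(h_harm,
                      setdiff(which(!is.na(mf) & abs(mf - k * f_h) <=
                                      harmonic_tol(k, f_h, abs_tol, rel_tol)),
                              c(h_idx, b_idx, b_harm)))
  }
  list(f_b = f_b, f_h = f_h,
       breathing_imf = b_idx,
       heartbeat_imfs = sort(c(h_idx, h_harm)),
       respiration = if (length(b_idx))
         sampled_signal(imfset$imfs[, b_idx], ts = imfset$ts) else zero_sig,
       pulsation = if (length(h_idx))
         sampled_signal(rowSums(imfset$imfs[, c(h_idx, h_harm), drop = FALSE]),
                        ts = imfset$ts) else zero_sig)
}
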