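#' Paired I/Q record from a CW Doppler sensor
#'
#' @param I,Q in-phase and quadrature samples (volts), equal length.
#' @param fs sampling rate in Hz.
#' @param wavelength carrier wavelength in meters (`c / f_carrier`; 24.17 GHz
#'   gives 12.4 mm).
#' @return object of class `"iq_record"`.
#' @export
iq_record <- function(I, Q, fs, wavelength) {
  I <- as.numeric(I); Q <- as.numeric(Q)
  if (length(I) != length(Q)) stop("I and Q must have equal length")
  if (!all(is.finite(I)) || !all(is.finite(Q))) stop("I/Q samples must be finite")
  if (fs <= 0) stop("'fs' must be positive")
  if (wavelength <= 0) stop("'wavelength' must be positive")
  structure(list(I = I, Q = Q, fs = fs, wavelength = wavelength),
            class = "iq_record")
}

#' @export
print.iq_record <- function(x, ...) {
  cat(sprintf("iq_record: %d samples at %g Hz, wavelength %.4g mm\n",
              length(x$I), x$fs, 1000 * x$wavelength))
  invisible(x)
}

#' Carrier wavelength from frequency in GHz
#'
#' @param f_ghz carrier frequency in GHz.
#' @return wavelength in meters.
#' @export
carrier_wavelength <- function(f_ghz) 299792458 / (f_ghz * 1e9)

#' I/Q imbalance parameters as an ellipse
#'
#' An ideal quadrature sensor traces a circle centered at the origin in the
#' I/Q plane; DC offsets, gain mismatch and quadrature phase error turn it
#' into an offset, rotated ellipse. `center` is the DC offset `(B_I, B_Q)`,
#' `gain_ratio = A_I / A_Q`, and `phase_offset` the deviation from quadrature
#' `Phi_I - Phi_Q` in radians. `axes` and `rotation` describe the fitted
#' ellipse geometry used by [correct_iq()].
#'
#' @param center numeric length-2 `(B_I, B_Q)` in volts.
#' @param axes semi-axes `(a, b)`, `a >= b`.
#' @param rotation major-axis angle in radians.
#' @param gain_ratio,phase_offset channel imbalance (see above).
#' @return object of class `"ellipse_params"`.
#' @export
ellipse_params <- function(center = c(0, 0), axes = c(1, 1), rotation = 0,
                           gain_ratio = 1, phase_offset = 0) {
  if (gain_ratio <= 0) stop("'gain_ratio' must be positive")
  structure(list(center = as.numeric(center), axes = as.numeric(axes),
                 rotation = as.numeric(rotation),
                 gain_ratio = as.numeric(gain_ratio),
                 phase_offset = as.numeric(phase_offset)),
            class = "ellipse_params")
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf(paste0("ellipse_params: center (%.4g, %.4g), axes (%.4g, %.4g), ",
                     "rotation %.3f rad\n  gain_ratio %.4g, phase_offset %.3f rad (%.2f deg)\n"),
              x$center[1], x$center[2], x$axes[1], x$axes[2], x$rotation,
              x$gain_ratio, x$phase_offset, 180 / pi * x$phase_offset))
  invisible(x)
}

#' Fit an ellipse to I/Q data by direct least squares
#'
#' Constrained direct least-squares conic fit (the numerically stable
#' Halir-Flusser form of the Fitzgibbon method): deterministic, needs only 5
#' distinct points, and always returns an ellipse when one exists. The conic
#' is decomposed into center, semi-axes and major-axis rotation, from which
#' the channel gain ratio and quadrature phase offset are recovered
#' (`A_I^2`, `A_Q^2` and `-A_I A_Q sin(Phi_I - Phi_Q)` are the entries of the
#' ellipse's shape matrix).
#'
#' @param iq an [iq_record()], or a two-column matrix of (I, Q) points.
#' @return an [ellipse_params()].
#' @examples
#' th <- seq(0, 2 * pi, length.out = 50)
#' fit_ellipse(cbind(cos(th), sin(th)))   # unit circle
#' @export
fit_ellipse <- function(iq) {
  if (inherits(iq, "iq_record")) pts <- cbind(iq$I, iq$Q) else pts <- as.matrix(iq)
  if (nrow(unique(pts)) < 5L) stop("ellipse fitting needs at least 5 distinct points")
  x <- pts[, 1]; y <- pts[, 2]
  # center/scale for conditioning; undo afterwards
  mx <- mean(x); my <- mean(y)
  sc <- max(stats::sd(x), stats::sd(y), 1e-12)
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate point set: conic fit is singular"))
  Mm <- S1 + S2 %*% Tm
  Mred <- rbind(Mm[3, ] / 2, -Mm[2, ], Mm[1, ] / 2)
  ev <- eigen(Mred)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) stop("degenerate point set: fitted conic is not an ellipse")
  a1 <- V[, ok[1]]
  coefs <- c(a1, drop(Tm %*% a1))          # A B C D E F in scaled coords
  # undo scaling: substitute xs = (x - mx)/sc, ys = (y - my)/sc
  A <- coefs[1] / sc^2; B <- coefs[2] / sc^2; C <- coefs[3] / sc^2
  D <- coefs[4] / sc - 2 * A * mx - B * my
  E <- coefs[5] / sc - 2 * C * my - B * mx
  F <- coefs[6] + A * mx^2 + B * mx * my + C * my^2 - coefs[4] * mx / sc -
    coefs[5] * my / sc
  M33 <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  ctr <- tryCatch(drop(-solve(M33, c(D / 2, E / 2))), error = function(e)
    stop("degenerate point set: fitted conic is not an ellipse"))
  F0 <- F + 0.5 * sum(c(D, E) * ctr)       # conic value at the center
  eg <- eigen(M33, symmetric = TRUE)
  if (any(eg$values * (-F0) <= 0))
    stop("degenerate point set: fitted conic is not an ellipse")
  semi <- sqrt(-F0 / eg$values)            # paired with eg$vectors columns
  major <- which.max(semi)
  axes <- c(semi[major], semi[-major])
  vmaj <- eg$vectors[, major]
  rotation <- atan2(vmaj[2], vmaj[1])
  if (rotation > pi / 2) rotation <- rotation - pi
  if (rotation <= -pi / 2) rotation <- rotation + pi
  # shape matrix MM' = -F0 * inv(M33) links geometry to channel imbalance
  MMt <- -F0 * solve(M33)
  A_I <- sqrt(MMt[1, 1]); A_Q <- sqrt(MMt[2, 2])
  sin_d <- -MMt[1, 2] / (A_I * A_Q)
  ellipse_params(center = ctr, axes = axes, rotation = rotation,
                 gain_ratio = A_I / A_Q,
                 phase_offset = asin(min(1, max(-1, sin_d))))
}

#' Correct I/Q imbalance using fitted ellipse parameters
#'
#' Applies, in order: center shift (DC offset removal), rotation by the
#' ellipse angle (phase imbalance), and per-axis rescaling to the geometric
#' mean radius (gain imbalance). The corrected points lie on a circle
#' centered at the origin, and because the correction is orientation
#' preserving (proper rotation, positive scales), the polar angle of the
#' corrected points equals the true modulation phase up to an additive
#' constant whenever `|phase_offset| < 90` degrees.
#'
#' @param iq an [iq_record()].
#' @param e an [ellipse_params()], typically from [fit_ellipse()].
#' @return an [iq_record()] on a centered circle.
#' @export
correct_iq <- function(iq, e) {
  stopifnot(inherits(iq, "iq_record"), inherits(e, "ellipse_params"))
  x <- iq$I - e$center[1]
  y <- iq$Q - e$center[2]
  cr <- cos(-e$rotation); sr <- sin(-e$rotation)
  u <- cr * x - sr * y
  v <- sr * x + cr * y
  rbar <- sqrt(prod(e$axes))
  iq_record(u * rbar / e$axes[1], v * rbar / e$axes[2],
            fs = iq$fs, wavelength = iq$wavelength)
}

#' Arctangent demodulation of corrected I/Q data
#'
#' Recovers target displacement as `r(t) = (lambda / 4 pi) * unwrap(atan2(Q, I))`.
#' The input must already lie on a centered circle (see [correct_iq()]); the
#' output is defined up to an additive constant, so only its AC part is
#' meaningful. Unwrapping makes displacements larger than `lambda / 4`
#' (multiple phase wraps) recoverable.
#'
#' @param iq an [iq_record()] on a centered circle.
#' @return a [sampled_signal()] in meters.
#' @export
arctangent_demodulate <- function(iq) {
  stopifnot(inherits(iq, "iq_record"))
  if (any(iq$I == 0 & iq$Q == 0)) stop("zero-radius I/Q sample: phase undefined")
  phase <- unwrap_phase(atan2(iq$Q, iq$I))
  sampled_signal(iq$wavelength / (4 * pi) * phase, ts = 1 / iq$fs, unit = "m")
}

#' CW pipeline: ellipse fit, correction, demodulation, decimation
#'
#' Convenience wrapper running [fit_ellipse()] (globally or per window),
#' [correct_iq()] and [arctangent_demodulate()], optionally followed by
#' [decimate_signal()] to the analysis rate.
#'
#' @param iq an [iq_record()].
#' @param fs_out optional output rate in Hz (default: keep input rate).
#' @param window_seconds optional per-window ellipse fitting; windows are
#'   demodulated independently and joined continuously at their boundaries.
#' @return a displacement [sampled_signal()] in meters.
#' @export
cw_to_displacement <- function(iq, fs_out = NULL, window_seconds = NULL) {
  stopifnot(inherits(iq, "iq_record"))
  if (is.null(window_seconds)) {
    r <- arctangent_demodulate(correct_iq(iq, fit_ellipse(iq)))
  } else {
    w <- max(2L, round(window_seconds * iq$fs))
    n <- length(iq$I)
    starts <- seq(1L, n, by = w)
    parts <- lapply(starts, function(s) {
      idx <- s:min(s + w - 1L, n)
      sub <- iq_record(iq$I[idx], iq$Q[idx], iq$fs, iq$wavelength)
      arctangent_demodulate(correct_iq(sub, fit_ellipse(sub)))$samples
    })
    for (i in seq_along(parts)[-1])        # join continuously
      parts[[i]] <- parts[[i]] - parts[[i]][1] + parts[[i - 1]][length(parts[[i - 1]])]
    r <- sampled_signal(unlist(parts), ts = 1 / iq$fs, unit = "m")
  }
  if (!is.null(fs_out)) r <- decimate_signal(r, fs_out)
  r
}
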