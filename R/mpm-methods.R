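#' @export
print.mpm <- function(x, ...) {
  cat(sprintf("Matrix pencil fit: %d poles (N = %d, Ts = %.6g s, L = %d, tol = %.3g)\n",
              nrow(x$poles), x$N, x$Ts, x$L, x$tol))
  if (nrow(x$poles)) {
    p <- x$poles[x$poles$f >= 0, , drop = FALSE]
    cat("Nonnegative-frequency poles:\n")
    print(data.frame(f_Hz = round(p$f, 4),
                     damping = signif(p$damping, 4),
                     amplitude = signif(Mod(p$residue), 4),
                     strength = signif(pole_strength(x)[as.integer(rownames(p))], 4)),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.mpm <- function(object, ...) {
  fit <- fitted(object)
  res <- object$y - fit
  rel <- if (rms(object$y) > 0) rms(res) / rms(object$y) else 0
  out <- list(model = object, rel_rms_residual = rel,
              n_pairs = sum(object$poles$f > 0),
              n_real = sum(object$poles$f == 0))
  class(out) <- "summary.mpm"
  out
}

#' @export
print.summary.mpm <- function(x, ...) {
  print(x$model)
  cat(sprintf("Conjugate pairs: %d, real poles: %d\n", x$n_pairs, x$n_real))
  cat(sprintf("Relative RMS reconstruction residual: %.3g\n", x$rel_rms_residual))
  invisible(x)
}

#' Pole table of a matrix pencil fit
#'
#' @param object an [mpm()] fit.
#' @param ... unused.
#' @return the pole data frame (`f`, `damping`, `residue`, `z`, `conj`).
#' @export
coef.mpm <- function(object, ...) object$poles

#' @export
fitted.mpm <- function(object, ...) {
  reconstruct(object)$samples
}

#' @export
residuals.mpm <- function(object, ...) object$y - fitted(object)

#' Predict (reconstruct) from a matrix pencil fit
#'
#' @param object an [mpm()] fit.
#' @param indices pole rows to use (closed under conjugation); default all.
#' @param n number of samples; default the fitted window length.
#' @param ... unused.
#' @return a [sampled_signal()].
#' @export
predict.mpm <- function(object, indices = NULL, n = NULL, ...) {
  reconstruct(object, indices = indices, n = n)
}

#' Pole plot of a matrix pencil fit
#'
#' Plots pole strength against frequency on a log scale, the standard view
#' for picking out breathing and heartbeat harmonic families.
#'
#' @param x an [mpm()] fit.
#' @param fmax largest frequency shown (Hz).
#' @param ... passed to [graphics::plot()].
#' @export
plot.mpm <- function(x, fmax = NULL, ...) {
  p <- x$poles[x$poles$f >= 0, , drop = FALSE]
  if (!nrow(p)) {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "frequency [Hz]",
                   ylab = "pole strength", main = "matrix pencil poles")
    return(invisible(x))
  }
  st <- pole_strength(x)[as.integer(rownames(p))]
  if (is.null(fmax)) fmax <- max(p$f) * 1.1 + 0.1
  graphics::plot(p$f, st, log = "y", type = "h", xlim = c(0, fmax),
                 xlab = "frequency [Hz]", ylab = "pole strength (window RMS)",
                 main = "matrix pencil poles", ...)
  graphics::points(p$f, st, pch = 19)
  invisible(x)
}

#' Simulate from a fitted exponential model
#'
#' Draws reconstructions plus white Gaussian noise with the residual standard
#' deviation of the fit.
#'
#' @param object an [mpm()] fit.
#' @param nsim number of series to simulate.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return a list of [sampled_signal()] objects of length `nsim`.
#' @export
simulate.mpm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  base <- fitted(object)
  sdr <- stats::sd(residuals(object))
  lapply(seq_len(nsim), function(i)
    sampled_signal(base + stats::rnorm(length(base), sd = sdr),
                   ts = object$Ts, t0 = object$t0))
}
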