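#' Extract respiration and heartbeat from a displacement signal
#'
#' The full pole-domain pipeline: fit the matrix pencil model, locate the
#' breathing pole and its harmonic family, subtract that family, keep the
#' 0.8-10 Hz poles, locate the heartbeat family, and reconstruct both the
#' respiration waveform (breathing family) and the artery-pulsation waveform
#' (heartbeat family). When `window_seconds` is given the signal is processed
#' per window (recommended: at least five cycles of the slowest component,
#' 12.5-20 s for resting breathing) and the per-window reconstructions are
#' stitched together.
#'
#' The key property of this route, in contrast to plain band-pass filtering,
#' is that breathing harmonics falling inside the heart band are removed by
#' *frequency membership* in the breathing family, not by amplitude, so a
#' third breathing harmonic that outweighs the heartbeat does not get
#' mistaken for it.
#'
#' @param y a [sampled_signal()] (displacement, meters) or numeric vector
#'   with `ts`.
#' @param breathing_band,heart_band frequency bands in Hz.
#' @param retain_band band kept after breathing removal (Hz).
#' @param n_harmonics harmonics searched for each family.
#' @param tol,L matrix pencil settings, see [mpm()].
#' @param ts sampling interval when `y` is a plain vector.
#' @param window_seconds,overlap_fraction optional segmentation, see
#'   [segment_signal()].
#' @param harmonic_check_heart enable the heartbeat harmonic-presence
#'   disambiguation (see [find_heartbeat()]).
#' @param abs_tol,rel_tol harmonic matching tolerance.
#' @return An object of class `"vital_estimate"`: list with
#'   \item{windows}{data frame of per-window `t0`, `f_b`, `f_h` (Hz).}
#'   \item{f_b, f_h}{median rates over windows (Hz; `NA` when never found).}
#'   \item{respiration, pulsation}{reconstructed [sampled_signal()]s.}
#'   \item{models}{list of per-window [mpm()] fits.}
#' @examples
#' cfg <- vital_config(duration = 20, snr_db = Inf, seed = 1)
#' d <- gen_displacement(cfg)
#' v <- extract_vitals(d$displacement)
#' c(v$f_b, v$f_h)
#' @export
extract_vitals <- function(y, breathing_band = c(0.1, 0.4), heart_band = c(0.8, 2),
                           retain_band = c(0.8, 10), n_harmonics = 4,
                           tol = 1e-4, L = NULL, ts = NULL,
                           window_seconds = NULL, overlap_fraction = 0,
                           harmonic_check_heart = FALSE,
                           abs_tol = 0.05, rel_tol = 0.04) {
  y <- as_sampled_signal(y, ts = ts)
  wins <- if (is.null(window_seconds)) list(y)
          else segment_signal(y, window_seconds, overlap_fraction)
  res <- lapply(wins, function(w) {
    fit <- mpm(w, tol = tol, L = L)
    br <- find_breathing(fit, band = breathing_band, n_harmonics = n_harmonics,
                         abs_tol = abs_tol, rel_tol = rel_tol)
    fit2 <- remove_family(fit, br$indices)
    fit2 <- band_retain(fit2, retain_band)
    hb <- find_heartbeat(fit2, band = heart_band, n_harmonics = n_harmonics,
                         harmonic_check = harmonic_check_heart,
                         abs_tol = abs_tol, rel_tol = rel_tol)
    list(fit = fit,
         f_b = br$f_b, f_h = hb$f_h,
         respiration = reconstruct(fit, br$indices),
         pulsation = reconstruct(fit2, hb$indices))
  })
  step <- if (length(wins) > 1L)
    round(length(wins[[1]]$samples) * (1 - overlap_fraction)) else NULL
  structure(list(
    windows = data.frame(t0 = vapply(wins, function(w) w$t0, 0),
                         f_b = vapply(res, function(r) r$f_b, 0),
                         f_h = vapply(res, function(r) r$f_h, 0)),
    f_b = stats::median(vapply(res, function(r) r$f_b, 0), na.rm = TRUE),
    f_h = stats::median(vapply(res, function(r) r$f_h, 0), na.rm = TRUE),
    respiration = stitch_windows(lapply(res, `[[`, "respiration"), step, y),
    pulsation = stitch_windows(lapply(res, `[[`, "pulsation"), step, y),
    models = lapply(res, `[[`, "fit")),
    class = "vital_estimate")
}

# join per-window reconstructions. Non-overlapping windows concatenate; with
# overlap the windows are cross-faded (weighted overlap-add with linear
# ramps), which suppresses stitch discontinuities that would otherwise leave
# spurious peaks in the joined waveform
stitch_windows <- function(parts, step, y) {
  if (length(parts) == 1L) return(parts[[1]])
  w <- length(parts[[1]]$samples)
  k <- length(parts)
  if (step >= w) {
    segs <- lapply(seq_along(parts), function(i) {
      x <- parts[[i]]$samples
      if (i < k) x[seq_len(min(step, w))] else x
    })
    return(sampled_signal(unlist(segs), ts = parts[[1]]$ts, t0 = parts[[1]]$t0))
  }
  ov <- min(w - step, w %/% 2)
  ramp <- seq(1 / (ov + 1), 1 - 1 / (ov + 1), length.out = ov)
  weight <- c(ramp, rep(1, w - 2 * ov), rev(ramp))
  total <- step * (k - 1L) + w
  num <- den <- numeric(total)
  for (i in seq_len(k)) {
    idx <- (i - 1L) * step + seq_len(w)
    num[idx] <- num[idx] + weight * parts[[i]]$samples
    den[idx] <- den[idx] + weight
  }
  sampled_signal(num / den, ts = parts[[1]]$ts, t0 = parts[[1]]$t0)
}

#' Beat detection tuned by the pipeline's own rate estimate
#'
#' Runs [detect_beats()] on the reconstructed pulsation of a
#' [extract_vitals()] result, centering the admissible rate window on the
#' estimated heart rate (`60 f_h / margin` to `60 f_h * margin`) and
#' trimming one nominal beat period from each window edge, where
#' reconstruction transients live.
#'
#' @param v a `"vital_estimate"` from [extract_vitals()].
#' @param margin multiplicative width of the admissible rate window.
#' @param prominence_frac see [detect_beats()].
#' @param edge_beats how many nominal beat periods to trim at each end.
#' @return a [beat_series()].
#' @export
vital_beats <- function(v, margin = 1.5, prominence_frac = 0.3,
                        edge_beats = 1) {
  stopifnot(inherits(v, "vital_estimate"))
  if (is.na(v$f_h)) stop("no heart rate estimate to guide beat detection")
  detect_beats(v$pulsation,
               min_rate = 60 * v$f_h / margin,
               max_rate = 60 * v$f_h * margin,
               prominence_frac = prominence_frac,
               edge_seconds = edge_beats / v$f_h,
               source = "mpm")
}

#' @export
print.vital_estimate <- function(x, ...) {
  cat("Vital-sign estimate (matrix pencil pipeline)\n")
  cat(sprintf("  breathing rate: %s Hz\n",
              if (is.na(x$f_b)) "not found" else sprintf("%.3f", x$f_b)))
  cat(sprintf("  heart rate:     %s Hz (%s bpm)\n",
              if (is.na(x$f_h)) "not found" else sprintf("%.3f", x$f_h),
              if (is.na(x$f_h)) "-" else sprintf("%.1f", 60 * x$f_h)))
  if (nrow(x$windows) > 1L) {
    cat(sprintf("  %d windows:\n", nrow(x$windows)))
    print(round(x$windows, 3), row.names = FALSE)
  }
  invisible(x)
}
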