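#' Beat series: detected beat times and beat-to-beat rates
#'
#' @param beat_times strictly increasing beat times in seconds.
#' @param source method label (e.g. "mpm", "ecg").
#' @return object of class `"beat_series"` with `beat_times`, `bpm`
#'   (60 / interval, one fewer than beats) and `source`.
#' @export
beat_series <- function(beat_times, source = "unknown") {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) >= 2L && any(diff(beat_times) <= 0))
    stop("beat times must be strictly increasing")
  structure(list(beat_times = beat_times,
                 bpm = if (length(beat_times) >= 2L) 60 / diff(beat_times) else numeric(0),
                 source = source),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("beat_series [%s]: %d beats", x$source, length(x$beat_times)))
  if (length(x$bpm))
    cat(sprintf(", mean %.1f bpm (range %.1f-%.1f)", mean(x$bpm),
                min(x$bpm), max(x$bpm)))
  cat("\n")
  invisible(x)
}

#' Detect beats in a reconstructed pulsation waveform
#'
#' Local maxima with (i) topographic prominence of at least
#' `prominence_frac` times the signal RMS and (ii) a minimum separation of
#' `60 / max_rate` seconds (enforced greedily from the tallest peak down).
#' Peak times are refined to sub-sample precision by parabolic interpolation
#' through the three samples around each maximum. Peak-to-peak intervals of
#' successive pulsations then give the beat-to-beat heart rate.
#'
#' @param pulsation a [sampled_signal()] band-limited around the heartbeat.
#' @param min_rate,max_rate admissible heart-rate range in beats/min.
#' @param prominence_frac prominence threshold as a fraction of signal RMS.
#' @param edge_seconds ignore peaks this close to either end of the window
#'   (reconstructed waveforms carry boundary transients).
#' @param source label stored on the result.
#' @return a [beat_series()]; empty (with a warning) when fewer than 2 peaks
#'   are found.
#' @export
detect_beats <- function(pulsation, min_rate = 40, max_rate = 180,
                         prominence_frac = 0.3, edge_seconds = 0,
                         source = "radar") {
  stopifnot(inherits(pulsation, "sampled_signal"))
  x <- pulsation$samples
  n <- length(x)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (edge_seconds > 0) {
    lo <- edge_seconds / pulsation$ts
    cand <- cand[cand > lo & cand <= n - lo]
  }
  if (length(cand)) {
    prom <- peak_prominence(x, cand)
    cand <- cand[prom >= prominence_frac * rms(x)]
  }
  # greedy minimum-separation suppression, tallest first
  min_sep <- ceiling((60 / max_rate) / pulsation$ts)
  keep <- integer(0)
  for (i in cand[order(-x[cand])]) {
    if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  if (length(keep) < 2L) {
    warning("fewer than 2 beats detected")
    return(beat_series(numeric(0), source = source))
  }
  # parabolic sub-sample refinement
  tt <- vapply(keep, function(i) {
    if (i <= 1L || i >= n) return((i - 1) * pulsation$ts)
    den <- x[i - 1] - 2 * x[i] + x[i + 1]
    delta <- if (abs(den) > 1e-300) 0.5 * (x[i - 1] - x[i + 1]) / den else 0
    (i - 1 + delta) * pulsation$ts
  }, 0)
  tt <- pulsation$t0 + tt
  ok <- c(TRUE, diff(tt) > 60 / (max_rate * 4))   # guard against refinement collisions
  beat_series(tt[ok], source = source)
}

# topographic prominence: height above the higher of the two lowest valleys
# separating the peak from the nearest higher terrain on each side
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1)]
    higher_l <- which(left > h)
    lo_l <- if (length(higher_l)) min(left[(max(higher_l) + 1):(i - 1)])
            else min(left)
    right <- x[(i + 1):length(x)]
    higher_r <- which(right > h)
    lo_r <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1)])
            else min(right)
    h - max(lo_l, lo_r)
  }, 0)
}

#' Beat-to-beat heart rate with interval midpoints
#'
#' @param series a [beat_series()].
#' @return data frame with `t` (interval midpoint, seconds) and `bpm`
#'   (60 / interval).
#' @export
beat_to_beat <- function(series) {
  stopifnot(inherits(series, "beat_series"))
  bt <- series$beat_times
  if (length(bt) < 2L) return(data.frame(t = numeric(0), bpm = numeric(0)))
  data.frame(t = (bt[-1] + bt[-length(bt)]) / 2, bpm = 60 / diff(bt))
}

#' Reject physiologically implausible beat-to-beat values
#'
#' Standard HRV artifact rejection: beat-to-beat entries implying a rate
#' outside `[60 f_ref / margin, 60 f_ref * margin]` come from missed or
#' spurious peaks (an interval doubles or halves) rather than true
#' variability, and are excluded before agreement scoring.
#'
#' @param rates data frame with `t` and `bpm`, as from [beat_to_beat()].
#' @param f_ref reference rate in Hz (e.g. the pipeline's heart-rate
#'   estimate).
#' @param margin multiplicative plausibility band around `60 * f_ref`.
#' @return the filtered data frame.
#' @export
plausible_rates <- function(rates, f_ref, margin = 1.3) {
  stopifnot(is.finite(f_ref), f_ref > 0)
  rates[rates$bpm >= 60 * f_ref / margin & rates$bpm <= 60 * f_ref * margin, ,
        drop = FALSE]
}

#' Agreement between an estimated and a reference rate sequence
#'
#' Pairs each estimated point with the nearest reference point in time
#' (rejecting pairs further apart than half the median reference interval)
#' and reports RMSE, bias (mean difference), Bland-Altman 95% limits of
#' agreement (`bias +- 1.96 sd`) and the Pearson correlation.
#'
#' @param est,ref data frames with columns `t` (seconds) and `bpm`, as from
#'   [beat_to_beat()], or [beat_series()] objects.
#' @return object of class `"agreement"` with `rmse`, `bias`, `loa`
#'   (length 2), `r`, `n_pairs`.
#' @export
compare_rates <- function(est, ref) {
  est <- as_rate_frame(est)
  ref <- as_rate_frame(ref)
  if (!nrow(est) || !nrow(ref)) stop("empty rate sequence")
  max_gap <- 0.5 * stats::median(diff(sort(ref$t)))
  if (!is.finite(max_gap) || max_gap <= 0) max_gap <- Inf
  idx <- vapply(est$t, function(t) which.min(abs(ref$t - t)), 0L)
  gap <- abs(ref$t[idx] - est$t)
  use <- gap <= max_gap
  if (!any(use)) stop("no estimate/reference pairs within the pairing window")
  d <- est$bpm[use] - ref$bpm[idx[use]]
  sdd <- if (length(d) > 1L) stats::sd(d) else 0
  r <- if (length(d) > 2L && stats::sd(est$bpm[use]) > 0 &&
           stats::sd(ref$bpm[idx[use]]) > 0)
    stats::cor(est$bpm[use], ref$bpm[idx[use]]) else NA_real_
  structure(list(rmse = sqrt(mean(d^2)), bias = mean(d),
                 loa = mean(d) + c(-1.96, 1.96) * sdd, r = r,
                 n_pairs = sum(use)),
            class = "agreement")
}

as_rate_frame <- function(x) {
  if (inherits(x, "beat_series")) return(beat_to_beat(x))
  stopifnot(is.data.frame(x), all(c("t", "bpm") %in% names(x)))
  x
}

#' @export
print.agreement <- function(x, ...) {
  cat(sprintf("agreement over %d pairs:\n", x$n_pairs))
  cat(sprintf("  RMSE  %.2f bpm\n  bias  %+.2f bpm\n  LoA   [%+.2f, %+.2f] bpm\n",
              x$rmse, x$bias, x$loa[1], x$loa[2]))
  if (!is.na(x$r)) cat(sprintf("  r     %.3f\n", x$r))
  invisible(x)
}
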