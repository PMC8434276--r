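#' Uniformly sampled real signal
#'
#' Lightweight container for a real-valued, uniformly sampled time series:
#' the common currency of every stage of the pipeline (displacement signals,
#' slow-time radargram rows, reconstructed respiration/pulsation waveforms).
#'
#' @param samples numeric vector of finite sample values (arbitrary units;
#'   meters for displacement signals).
#' @param ts sampling interval in seconds (`ts > 0`).
#' @param t0 time of the first sample in seconds.
#' @param unit optional unit label carried along for printing.
#'
#' @return An object of class `"sampled_signal"`: a list with elements
#'   `samples`, `ts`, `t0`, `unit`.
#' @examples
#' y <- sampled_signal(sin(2 * pi * 1 * seq(0, 5, by = 0.02)), ts = 0.02)
#' y
#' @export
sampled_signal <- function(samples, ts, t0 = 0, unit = NULL) {
  samples <- as.numeric(samples)
  if (!is.numeric(ts) || length(ts) != 1L || !is.finite(ts) || ts <= 0)
    stop("'ts' must be a single positive number (seconds)")
  if (length(samples) < 2L)
    stop("a sampled_signal needs at least 2 samples")
  if (!all(is.finite(samples)))
    stop("all samples must be finite")
  structure(list(samples = samples, ts = ts, t0 = as.numeric(t0), unit = unit),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("sampled_signal: %d samples at %.6g Hz (ts = %.6g s), t0 = %.6g s%s\n",
              length(x$samples), 1 / x$ts, x$ts, x$t0,
              if (!is.null(x$unit)) paste0(", unit = ", x$unit) else ""))
  invisible(x)
}

#' @export
length.sampled_signal <- function(x) length(x$samples)

#' Time axis of a sampled signal
#'
#' @param y a [sampled_signal()].
#' @return numeric vector of sample times in seconds.
#' @export
signal_time <- function(y) {
  stopifnot(inherits(y, "sampled_signal"))
  y$t0 + (seq_along(y$samples) - 1) * y$ts
}

# coerce numeric vectors (with ts) or pass sampled_signal through
as_sampled_signal <- function(y, ts = NULL, t0 = 0) {
  if (inherits(y, "sampled_signal")) return(y)
  if (is.null(ts)) stop("'ts' must be given when 'y' is a plain numeric vector")
  sampled_signal(y, ts = ts, t0 = t0)
}

#' Split a signal into (possibly overlapping) analysis windows
#'
#' Fixed-length consecutive windows with a stated fractional overlap. Each
#' window carries its own start time `t0`; a trailing partial window is
#' dropped. For pole-based analysis the window should contain at least five
#' cycles of the slowest component of interest (12.5-20 s when breathing down
#' to 0.25 Hz is targeted).
#'
#' @param y a [sampled_signal()].
#' @param window_seconds window length in seconds; `window_seconds / y$ts >= 2`
#'   and no longer than the signal.
#' @param overlap_fraction fraction in `[0, 1)` of each window shared with the
#'   next.
#' @return list of [sampled_signal()] windows.
#' @examples
#' y <- sampled_signal(rnorm(2750), ts = 0.02)     # 55 s at 50 Hz
#' length(segment_signal(y, 12.5))                 # 4 windows of 625 samples
#' @export
segment_signal <- function(y, window_seconds, overlap_fraction = 0) {
  y <- as_sampled_signal(y)
  if (!is.finite(overlap_fraction) || overlap_fraction < 0 || overlap_fraction >= 1)
    stop("'overlap_fraction' must be in [0, 1)")
  n <- length(y$samples)
  w <- round(window_seconds / y$ts)
  if (w < 2) stop("window too short: fewer than 2 samples")
  if (w > n) stop("window longer than signal")
  step <- max(1L, round(w * (1 - overlap_fraction)))
  starts <- seq(1L, n - w + 1L, by = step)
  lapply(starts, function(s) {
    sampled_signal(y$samples[s:(s + w - 1L)], ts = y$ts,
                   t0 = y$t0 + (s - 1L) * y$ts, unit = y$unit)
  })
}

#' Decimate a signal to a lower sampling rate
#'
#' Zero-phase anti-alias low-pass filtering (Butterworth, applied
#' forward-backward) followed by downsampling. Large factors are split into
#' stages of at most 8 so the filter polynomials stay well conditioned; the
#' cutoff of each stage is 80% of the next stage's Nyquist frequency. Used to
#' bring 2000 Hz CW recordings to a rate (default 50 Hz) at which the Hankel
#' SVD of the pencil estimator is cheap while all vital-sign harmonics up to
#' 20 Hz survive.
#'
#' @param y a [sampled_signal()].
#' @param fs_new target sampling rate in Hz; the current rate must be an
#'   integer multiple of it.
#' @param order Butterworth order per stage.
#' @return a [sampled_signal()] at rate `fs_new`.
#' @export
decimate_signal <- function(y, fs_new, order = 6) {
  y <- as_sampled_signal(y)
  fs <- 1 / y$ts
  q <- fs / fs_new
  if (abs(q - round(q)) > 1e-8) stop("current rate must be an integer multiple of 'fs_new'")
  q <- as.integer(round(q))
  if (q == 1L) return(y)
  stages <- integer(0)
  rest <- q
  while (rest > 1L) {                       # greedy factor split, each <= 8
    f <- min(rest, 8L)
    while (rest %% f != 0L) f <- f - 1L
    stages <- c(stages, f)
    rest <- rest %/% f
  }
  x <- y$samples
  fs_cur <- fs
  for (f in stages) {
    fs_next <- fs_cur / f
    wc <- 0.8 * (fs_next / 2) / (fs_cur / 2)
    bf <- signal::butter(order, wc, type = "low")
    x <- signal::filtfilt(bf, x)
    x <- x[seq(1L, length(x), by = f)]
    fs_cur <- fs_next
  }
  sampled_signal(x, ts = 1 / fs_new, t0 = y$t0, unit = y$unit)
}

rms <- function(x) sqrt(mean(x^2))

# phase unwrapping with the standard +-pi jump rule
unwrap_phase <- function(p) {
  if (length(p) < 2L) return(p)
  dp <- diff(p)
  jumps <- -2 * pi * round(dp / (2 * pi))
  p + c(0, cumsum(dp + jumps)) - c(0, cumsum(dp))
}
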