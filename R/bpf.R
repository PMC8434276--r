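#' Band-pass heartbeat extraction (conventional baseline)
#'
#' Zero-phase Butterworth band-pass (applied forward-backward with
#' `signal::filtfilt`, so in-band peak times are unshifted). This is the
#' weakest of the three extraction routes: whatever is strongest inside the
#' heart band is kept, so a large breathing harmonic inside the band is
#' mistaken for the heartbeat.
#'
#' @param y a [sampled_signal()] or numeric vector with `ts`.
#' @param band numeric length-2 pass band in Hz; the upper edge must lie
#'   below Nyquist.
#' @param order Butterworth order (the forward-backward pass doubles the
#'   effective attenuation).
#' @param ts sampling interval when `y` is a plain vector.
#' @return a filtered [sampled_signal()].
#' @export
bandpass_extract <- function(y, band = c(0.8, 2), order = 4, ts = NULL) {
  y <- as_sampled_signal(y, ts = ts)
  fs <- 1 / y$ts
  if (band[2] >= fs / 2) stop("band upper edge must be below the Nyquist frequency")
  if (band[1] <= 0 || band[1] >= band[2]) stop("invalid band")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  sampled_signal(signal::filtfilt(bf, y$samples), ts = y$ts, t0 = y$t0,
                 unit = y$unit)
}

#' Dominant frequency of a signal
#'
#' Frequency of the periodogram maximum, refined by parabolic interpolation
#' of the log-spectrum around the peak. Used to show which component a
#' band-pass output locks onto.
#'
#' @param y a [sampled_signal()] or numeric vector with `ts`.
#' @param ts sampling interval when `y` is a plain vector.
#' @return frequency in Hz.
#' @export
dominant_frequency <- function(y, ts = NULL) {
  y <- as_sampled_signal(y, ts = ts)
  x <- y$samples - mean(y$samples)
  n <- length(x)
  sp <- Mod(stats::fft(x))[seq_len(n %/% 2)]
  i <- which.max(sp)
  df <- 1 / (n * y$ts)
  if (i > 1 && i < length(sp)) {
    la <- log(sp[i - 1] + 1e-300); lb <- log(sp[i] + 1e-300); lc <- log(sp[i + 1] + 1e-300)
    den <- la - 2 * lb + lc
    delta <- if (abs(den) > 1e-12) 0.5 * (la - lc) / den else 0
    (i - 1 + delta) * df
  } else {
    (i - 1) * df
  }
}
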