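#' Radargram (fast-time x slow-time matrix) from a UWB impulse sensor
#'
#' Each column is one recorded impulse response (fast time, sub-nanosecond
#' steps); each row follows one range bin over observation time (slow time,
#' sub-second steps).
#'
#' @param values numeric `P x N` matrix, `P` range bins by `N` observations.
#' @param fast_time_step fast-time step in seconds (the reciprocal of the
#'   sensor clock; 1/13 GHz for the device this models).
#' @param slow_time_step slow-time step in seconds (0.02 s at 50 Hz).
#' @return object of class `"radargram"`.
#' @export
radargram <- function(values, fast_time_step, slow_time_step = 0.02) {
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values)))
    stop("radargram values must be finite numeric")
  if (nrow(values) < 1L || ncol(values) < 2L)
    stop("radargram needs P >= 1 range bins and N >= 2 observations")
  if (fast_time_step <= 0 || slow_time_step <= 0)
    stop("time steps must be positive")
  structure(list(values = values, fast_time_step = fast_time_step,
                 slow_time_step = slow_time_step),
            class = "radargram")
}

#' @export
print.radargram <- function(x, ...) {
  cat(sprintf("radargram: %d range bins x %d observations (fast %.3g ns, slow %.3g s)\n",
              nrow(x$values), ncol(x$values), 1e9 * x$fast_time_step,
              x$slow_time_step))
  invisible(x)
}

#' @export
dim.radargram <- function(x) dim(x$values)

#' Remove static clutter from a radargram
#'
#' Antenna crosstalk, walls and stationary body parts are constant over slow
#' time; subtracting each range bin's slow-time mean removes them. Output row
#' means are zero to machine precision; column-to-column differences within a
#' row are unchanged.
#'
#' @param R a [radargram()].
#' @return a [radargram()] with zero-mean rows.
#' @export
remove_static_clutter <- function(R) {
  stopifnot(inherits(R, "radargram"))
  R$values <- R$values - rowMeans(R$values)
  R
}

#' Cross-correlation motion compensation
#'
#' Bulk subject motion shifts the whole impulse response across range bins.
#' Each column is circularly cross-correlated with a reference column and
#' circularly shifted by the lag maximizing the correlation, aligning all
#' columns with the reference. Exact ties are broken toward the
#' smallest-magnitude lag, negative before positive. Apply after static
#' clutter removal; on noiseless input a second pass yields all-zero shifts.
#'
#' @param R a [radargram()] (clutter removed).
#' @param reference_index column used as the alignment reference (default the
#'   first).
#' @return list with `radargram` (aligned) and `shifts` (integer lag applied
#'   to each column).
#' @export
motion_compensate <- function(R, reference_index = 1L) {
  stopifnot(inherits(R, "radargram"))
  V <- R$values
  P <- nrow(V)
  ref <- V[, reference_index]
  if (all(ref == 0)) stop("reference column is all zero")
  Fr <- stats::fft(ref)
  # lag ordering for tie-breaks: 0, -1, +1, -2, +2, ...
  lags <- as.integer(c(0, rbind(-seq_len(P %/% 2), seq_len(P %/% 2))))[seq_len(P)]
  shifts <- integer(ncol(V))
  out <- V
  for (j in seq_len(ncol(V))) {
    cc <- Re(stats::fft(stats::fft(V[, j]) * Conj(Fr), inverse = TRUE)) / P
    # cc[m + 1] is the correlation after shifting column j by lag m (circular)
    cl <- cc[((-lags) %% P) + 1L]
    best <- lags[which(cl >= max(cl) - 1e-12 * max(abs(cl)))][1]
    shifts[j] <- best
    out[, j] <- circ_shift(V[, j], best)
  }
  R$values <- out
  list(radargram = R, shifts = shifts)
}

# shift x down by s positions, circularly: out[m] = x[m - s]
circ_shift <- function(x, s) {
  n <- length(x)
  s <- ((s %% n) + n) %% n
  if (s == 0) return(x)
  c(x[(n - s + 1):n], x[1:(n - s)])
}

#' Select the target range bin
#'
#' The range bin whose slow-time standard deviation is largest carries the
#' strongest vital-sign modulation and is selected as the target bin. Ties go
#' to the lowest index. Run after clutter removal (and motion compensation if
#' the subject moves).
#'
#' @param R a [radargram()].
#' @return integer row index of the target range bin.
#' @export
select_range_bin <- function(R) {
  stopifnot(inherits(R, "radargram"))
  sds <- apply(R$values, 1, stats::sd)
  which.max(sds)
}

#' Extract the slow-time signal of one range bin
#'
#' @param R a [radargram()].
#' @param m row (range bin) index.
#' @return a [sampled_signal()] with `ts` equal to the slow-time step.
#' @export
extract_slow_time <- function(R, m) {
  stopifnot(inherits(R, "radargram"))
  if (m < 1L || m > nrow(R$values)) stop("range bin index out of range")
  sampled_signal(R$values[m, ], ts = R$slow_time_step)
}

#' UWB pipeline: clutter removal, motion compensation, bin selection
#'
#' Runs the preprocessing chain in the order clutter removal, optional
#' motion compensation, range-bin selection, slow-time extraction.
#'
#' @param R a [radargram()].
#' @param compensate_motion apply cross-correlation alignment (for moving
#'   subjects).
#' @return list with `signal` (a [sampled_signal()]), `bin` (selected row),
#'   and `shifts` (or `NULL`).
#' @export
uwb_to_signal <- function(R, compensate_motion = FALSE) {
  R <- remove_static_clutter(R)
  shifts <- NULL
  if (compensate_motion) {
    mc <- motion_compensate(R)
    R <- mc$radargram
    shifts <- mc$shifts
  }
  m <- select_range_bin(R)
  list(signal = extract_slow_time(R, m), bin = m, shifts = shifts)
}
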