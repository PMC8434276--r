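#' Configuration of a synthetic vital-sign scenario
#'
#' Defines the ground truth for generated displacement signals: a breathing
#' harmonic series, a heartbeat harmonic series locked to a jittered beat
#' schedule (so beat-to-beat variability has a known truth), additive white
#' noise at a stated SNR, and a seed for bit-identical reproducibility.
#'
#' Default amplitudes emulate chest-wall measurement: a 2 mm breathing
#' fundamental with harmonics decaying to 0.4 mm at the 4th (so even the
#' 4th breathing harmonic outweighs the heartbeat, the regime in which plain
#' band-pass extraction fails) and a 0.3 mm heartbeat fundamental with three
#' weaker harmonics.
#'
#' @param f_breath breathing rate in Hz, in `(0, 0.8]`.
#' @param breath_amps breathing harmonic amplitudes in meters
#'   (fundamental first).
#' @param f_heart heart rate: a constant in Hz (in `(0.5, 4)`) or a function
#'   of time returning Hz (a schedule).
#' @param heart_amps heartbeat harmonic amplitudes in meters.
#' @param hrv_jitter multiplicative beat-interval noise (fractional sd).
#' @param duration length in seconds.
#' @param fs sampling rate in Hz.
#' @param snr_db additive white-noise SNR in dB (`Inf` = noiseless).
#' @param seed integer RNG seed.
#' @return object of class `"vital_config"`.
#' @export
vital_config <- function(f_breath = 0.3,
                         breath_amps = c(2e-3, 8e-4, 5e-4, 4e-4),
                         f_heart = 1.1,
                         heart_amps = c(3e-4, 1.5e-4, 7e-5, 3e-5),
                         hrv_jitter = 0.02,
                         duration = 30, fs = 50, snr_db = 20, seed = 1) {
  if (is.numeric(f_heart)) {
    if (f_heart <= 0.5 || f_heart >= 4) stop("'f_heart' must lie in (0.5, 4) Hz")
  } else if (!is.function(f_heart)) stop("'f_heart' must be a number or function of time")
  if (f_breath <= 0 || f_breath > 0.8) stop("'f_breath' must lie in (0, 0.8] Hz")
  if (any(breath_amps < 0) || any(heart_amps < 0)) stop("amplitudes must be >= 0")
  structure(list(f_breath = f_breath, breath_amps = breath_amps,
                 f_heart = f_heart, heart_amps = heart_amps,
                 hrv_jitter = hrv_jitter, duration = duration, fs = fs,
                 snr_db = snr_db, seed = as.integer(seed)),
            class = "vital_config")
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

heart_rate_fun <- function(cfg) {
  if (is.function(cfg$f_heart)) cfg$f_heart else function(t) rep(cfg$f_heart, length(t))
}

#' Generate a ground-truth displacement signal
#'
#' Breathing is a cosine harmonic series at `k * f_breath` with seeded random
#' phases. The heartbeat is a harmonic series in the *beat phase*
#' `phi(t)` (piecewise-linear, incrementing by 1 at each beat), where the
#' beat schedule integrates the heart-rate track with multiplicative
#' interval jitter; all heart harmonics peak together at each beat time, so
#' the programmed schedule is the beat-detection ground truth. White noise is
#' added to the stated SNR (relative to the clean signal power).
#'
#' @param cfg a [vital_config()].
#' @return list with `displacement` (a [sampled_signal()] in meters),
#'   `beat_times` (seconds), `f_breath`, and `f_heart_track` (Hz per sample).
#' @export
gen_displacement <- function(cfg) {
  stopifnot(inherits(cfg, "vital_config"))
  with_seed(cfg$seed, {
    n <- round(cfg$duration * cfg$fs)
    t <- (seq_len(n) - 1) / cfg$fs
    fh <- heart_rate_fun(cfg)
    # breathing harmonic series
    breath <- rep(0, n)
    if (any(cfg$breath_amps > 0)) {
      ph <- stats::runif(length(cfg$breath_amps), 0, 2 * pi)
      for (k in seq_along(cfg$breath_amps))
        breath <- breath + cfg$breath_amps[k] *
          cos(2 * pi * k * cfg$f_breath * t + ph[k])
    }
    # jittered beat schedule from the heart-rate track
    beats <- numeric(0)
    if (any(cfg$heart_amps > 0)) {
      tb <- 0
      while (tb < cfg$duration) {
        beats <- c(beats, tb)
        interval <- 1 / fh(tb)
        if (cfg$hrv_jitter > 0)
          interval <- interval * max(0.2, 1 + cfg$hrv_jitter * stats::rnorm(1))
        tb <- tb + interval
      }
    }
    heart <- rep(0, n)
    if (length(beats) >= 2L) {
      # beat phase: 0, 1, 2, ... at beat times, linear in between
      phi <- stats::approx(beats, seq_along(beats) - 1, xout = t, rule = 2)$y
      for (k in seq_along(cfg$heart_amps))
        heart <- heart + cfg$heart_amps[k] * cos(2 * pi * k * phi)
    }
    clean <- breath + heart
    noise <- rep(0, n)
    if (is.finite(cfg$snr_db) && rms(clean) > 0) {
      sdn <- rms(clean) * 10^(-cfg$snr_db / 20)
      noise <- stats::rnorm(n, sd = sdn)
    }
    list(displacement = sampled_signal(clean + noise, ts = 1 / cfg$fs, unit = "m"),
         beat_times = beats,
         f_breath = cfg$f_breath,
         f_heart_track = fh(t))
  })
}

#' CW I/Q imbalance settings for the forward model
#'
#' Raw channel parameters of the quadrature forward model
#' `I = A_I cos(4 pi r / lambda + Phi_I) + B_I`,
#' `Q = A_Q sin(4 pi r / lambda + Phi_Q) + B_Q`.
#'
#' @param B_I,B_Q DC offsets (volts).
#' @param A_I,A_Q channel gains (volts).
#' @param phi_I,phi_Q channel phases (radians); `phi_I - phi_Q` is the
#'   quadrature phase error.
#' @return a plain list with class `"cw_imbalance"`.
#' @export
cw_imbalance <- function(B_I = 0, B_Q = 0, A_I = 1, A_Q = 1,
                         phi_I = 0, phi_Q = 0) {
  structure(list(B_I = B_I, B_Q = B_Q, A_I = A_I, A_Q = A_Q,
                 phi_I = phi_I, phi_Q = phi_Q),
            class = "cw_imbalance")
}

#' Generate CW sensor I/Q data from a displacement signal
#'
#' Exact forward evaluation of the quadrature model with the stated
#' imbalance, plus optional white noise per channel. With identity imbalance
#' and no noise, [arctangent_demodulate()] inverts it exactly (up to an
#' additive constant).
#'
#' @param r a displacement [sampled_signal()] in meters.
#' @param wavelength carrier wavelength in meters (default the 24.17 GHz
#'   carrier).
#' @param imbalance a [cw_imbalance()].
#' @param snr_db per-channel SNR in dB (`Inf` = noiseless), relative to the
#'   AC power of each channel.
#' @param seed RNG seed for the noise.
#' @return an [iq_record()].
#' @export
gen_cw_iq <- function(r, wavelength = carrier_wavelength(24.17),
                      imbalance = cw_imbalance(), snr_db = Inf, seed = 1) {
  stopifnot(inherits(r, "sampled_signal"), inherits(imbalance, "cw_imbalance"))
  with_seed(seed, {
    th <- 4 * pi * r$samples / wavelength
    I <- imbalance$A_I * cos(th + imbalance$phi_I) + imbalance$B_I
    Q <- imbalance$A_Q * sin(th + imbalance$phi_Q) + imbalance$B_Q
    if (is.finite(snr_db)) {
      I <- I + stats::rnorm(length(I), sd = rms(I - mean(I)) * 10^(-snr_db / 20))
      Q <- Q + stats::rnorm(length(Q), sd = rms(Q - mean(Q)) * 10^(-snr_db / 20))
    }
    iq_record(I, Q, fs = 1 / r$ts, wavelength = wavelength)
  })
}

#' Generate a UWB radargram from a displacement signal
#'
#' Each slow-time column is a static clutter profile (an antenna-crosstalk
#' pulse plus a smooth background) plus a Gaussian-modulated sinusoid echo
#' centered at `target_delay`, whose time of arrival and amplitude are both
#' modulated by the displacement (the delay shift is `2 r / c`, evaluated
#' analytically so sub-bin shifts are exact), an optional integer-bin bulk
#' motion shift, and white noise scaled to the stated SNR of the modulated
#' (clutter-free) part.
#'
#' @param r a displacement [sampled_signal()] in meters (slow-time rate).
#' @param P number of range bins.
#' @param fast_time_step fast-time step in seconds (default 1/13 GHz).
#' @param target_delay echo center in seconds of fast time.
#' @param pulse_width Gaussian envelope sigma in seconds (~2 ns total span by
#'   default).
#' @param pulse_freq carrier of the echo pulse in Hz.
#' @param amp_mod fractional amplitude modulation at the displacement peak.
#' @param clutter_scale amplitude of the static clutter relative to the echo.
#' @param bulk_shifts integer vector (length N) of bulk-motion bin shifts, or
#'   `NULL` for a stationary subject.
#' @param snr_db SNR of the additive noise in dB (`Inf` = noiseless).
#' @param seed RNG seed for the noise.
#' @return a [radargram()].
#' @export
gen_radargram <- function(r, P = 80, fast_time_step = 1 / 13e9,
                          target_delay = 1.2e-9, pulse_width = 5e-10,
                          pulse_freq = 1.5e9, amp_mod = 0.3,
                          clutter_scale = 5, bulk_shifts = NULL,
                          snr_db = Inf, seed = 1) {
  stopifnot(inherits(r, "sampled_signal"))
  with_seed(seed, {
    n <- length(r$samples)
    tau <- (seq_len(P) - 1) * fast_time_step
    pulse <- function(tt) exp(-(tt / pulse_width)^2) * cos(2 * pi * pulse_freq * tt)
    # static clutter: crosstalk pulse near zero delay + smooth baseline
    clutter <- clutter_scale * pulse(tau - 0.4e-9) +
      0.2 * clutter_scale * exp(-tau / 2e-9)
    x <- r$samples
    xsc <- max(abs(x), 1e-300)
    delay_shift <- 2 * x / 299792458
    V <- matrix(0, P, n)
    if (!is.null(bulk_shifts) && length(bulk_shifts) != n)
      stop("'bulk_shifts' must have one entry per column")
    for (j in seq_len(n)) {
      a <- 1 + amp_mod * x[j] / xsc
      echo <- a * pulse(tau - target_delay - delay_shift[j])
      if (!is.null(bulk_shifts))            # subject moves; clutter stays static
        echo <- circ_shift(echo, as.integer(bulk_shifts[j]))
      V[, j] <- clutter + echo
    }
    if (is.finite(snr_db)) {
      mod_part <- V - rowMeans(V)
      sdn <- rms(as.numeric(mod_part)) * 10^(-snr_db / 20)
      V <- V + matrix(stats::rnorm(P * n, sd = sdn), P, n)
    }
    radargram(V, fast_time_step = fast_time_step, slow_time_step = r$ts)
  })
}
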