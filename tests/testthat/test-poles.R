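# pole post-processing on hand-built models (see helper-synth.R) and on
# decompositions of generated displacement signals

test_that("breathing is the strongest in-band pole with its harmonic family", {
  m <- make_pole_model(f = c(0.3, 0.6, 0.9, 1.2, 1.83),
                       amp = c(1.0, 0.5, 0.3, 0.2, 0.1))
  br <- find_breathing(m)
  expect_true(br$found)
  expect_equal(br$f_b, 0.3)
  expect_setequal(m$poles$f[br$indices],
                  c(-1.2, -0.9, -0.6, -0.3, 0.3, 0.6, 0.9, 1.2))
  # removing the family leaves only the heartbeat pair
  left <- remove_family(m, br$indices)
  expect_setequal(left$poles$f, c(-1.83, 1.83))
})

test_that("breathing degenerate branches behave", {
  single <- make_pole_model(0.25, 1)
  br <- find_breathing(single)
  expect_equal(br$f_b, 0.25)
  expect_setequal(single$poles$f[br$indices], c(-0.25, 0.25))
  none <- find_breathing(make_pole_model(c(0.5, 1.2), c(1, 1)))
  expect_false(none$found)
  expect_true(is.na(none$f_b))
  expect_length(none$indices, 0L)
})

test_that("family removal drops exactly the named poles", {
  m <- make_pole_model(c(0.3, 0.9, 1.5), c(1, 0.5, 0.2))
  all_idx <- seq_len(nrow(m$poles))
  expect_identical(nrow(remove_family(m, all_idx)$poles), 0L)
  expect_identical(remove_family(m, integer(0)), m)
  kept <- remove_family(m, which(abs(m$poles$f) == 0.3))
  expect_setequal(kept$poles$f, c(-1.5, -0.9, 0.9, 1.5))
  expect_error(remove_family(m, which(m$poles$f == 0.3)), "conjugation")
})

test_that("band retention keeps conjugate pairs inside the band", {
  m <- make_pole_model(c(0.3, 1.83, 12), c(1, 0.5, 0.2))
  kept <- band_retain(m, c(0.8, 10))
  expect_setequal(kept$poles$f, c(-1.83, 1.83))
})

test_that("heartbeat selection collects its harmonic family", {
  m <- make_pole_model(c(1.83, 3.66, 5.49), c(0.1, 0.04, 0.01))
  hb <- find_heartbeat(m)
  expect_equal(hb$f_h, 1.83)
  expect_length(hb$indices, 6L)
  # exercise band shift
  m2 <- make_pole_model(1.6, 0.2)
  hb2 <- find_heartbeat(m2, band = c(1, 2.2))
  expect_equal(hb2$f_h, 1.6)
  # empty band
  none <- find_heartbeat(make_pole_model(0.3, 1))
  expect_false(none$found)
})

test_that("the harmonic-presence check skips candidates without harmonics", {
  m <- make_pole_model(c(0.9, 1.2, 2.4), c(0.5, 0.2, 0.1))
  plain <- find_heartbeat(m, harmonic_check = FALSE)
  expect_equal(plain$f_h, 0.9)
  checked <- find_heartbeat(m, harmonic_check = TRUE)
  expect_equal(checked$f_h, 1.2)
  expect_setequal(m$poles$f[checked$indices], c(-2.4, -1.2, 1.2, 2.4))
})

test_that("heartbeat choice ignores amplitudes of already-removed breathing", {
  for (third_amp in c(0.05, 0.4, 2)) {       # 3rd breathing harmonic in heart band
    m <- make_pole_model(c(0.32, 0.64, 0.96, 1.4), c(1, 0.5, third_amp, 0.12))
    br <- find_breathing(m)
    left <- remove_family(m, br$indices)
    hb <- find_heartbeat(left)
    expect_equal(hb$f_h, 1.4)
  }
})

test_that("the pipeline separates breathing and heartbeat on clean synthetics", {
  # the canonical resting scenario: 0.3 Hz breathing, 1.25 Hz heartbeat,
  # noiseless (no additive noise, no interval jitter)
  cfg <- vital_config(f_heart = 1.25, hrv_jitter = 0, duration = 30,
                      snr_db = Inf, seed = 3)
  d <- gen_displacement(cfg)
  v <- extract_vitals(d$displacement)
  expect_lt(abs(v$f_b - 0.3), 0.005)
  expect_lt(abs(v$f_h - 1.25), 0.005)
  expect_model_invariants(v$models[[1]])
})

test_that("breathing/heartbeat families are disjoint and additive", {
  cfg <- vital_config(duration = 30, snr_db = 25, seed = 6)
  d <- gen_displacement(cfg)
  fit <- mpm(d$displacement, tol = 1e-2)
  br <- find_breathing(fit)
  left <- remove_family(fit, br$indices)
  hb <- find_heartbeat(left)
  hb_orig <- which(fit$poles$z %in% left$poles$z[hb$indices])
  expect_length(intersect(br$indices, hb_orig), 0L)
  expect_true(all(c(br$indices, hb_orig) %in% seq_len(nrow(fit$poles))))
  # respiration + pulsation + remainder == full reconstruction
  rest <- setdiff(seq_len(nrow(fit$poles)), c(br$indices, hb_orig))
  total <- reconstruct(fit, br$indices)$samples +
    reconstruct(fit, hb_orig)$samples + reconstruct(fit, rest)$samples
  full <- reconstruct(fit)$samples
  expect_lt(rms(total - full) / rms(full), 1e-9)
})

test_that("a heartbeat-only signal reports no breathing and zero respiration", {
  cfg <- vital_config(breath_amps = rep(0, 4), duration = 20, snr_db = Inf,
                      seed = 2)
  d <- gen_displacement(cfg)
  v <- extract_vitals(d$displacement)
  expect_true(is.na(v$f_b))
  expect_equal(v$f_h, 1.1, tolerance = 0.02)
  expect_equal(rms(v$respiration$samples), 0)
})

test_that("a breathing harmonic close to the heartbeat is removed by family
           membership, not amplitude", {
  # third harmonic of 0.6 Hz breathing at 1.8 Hz, stronger than the 1.6 Hz
  # heartbeat, and inside the exercise heart band
  cfg <- vital_config(f_breath = 0.6, breath_amps = c(3e-3, 4e-4, 8e-4, 1.5e-4),
                      f_heart = 1.6, duration = 30, snr_db = Inf, seed = 8)
  d <- gen_displacement(cfg)
  v <- extract_vitals(d$displacement, breathing_band = c(0.1, 0.8),
                      heart_band = c(1, 2.2))
  expect_equal(v$f_h, 1.6, tolerance = 0.02)
})
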