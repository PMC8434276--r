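std_imbalance <- function() {
  cw_imbalance(B_I = 0.2, B_Q = -0.1, A_I = 1.2, A_Q = 1.0,
               phi_I = 10 * pi / 180, phi_Q = 0)
}

# displacement spanning well over a quarter wavelength
wide_displacement <- function(n = 2000, fs = 200) {
  t <- (seq_len(n) - 1) / fs
  sampled_signal(1.5e-3 * sin(2 * pi * 0.3 * t) + 4e-4 * sin(2 * pi * 1.2 * t + 1),
                 ts = 1 / fs, unit = "m")
}

test_that("a unit circle fits as an ideal sensor", {
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  e <- fit_ellipse(cbind(cos(th), sin(th)))
  expect_equal(e$center, c(0, 0), tolerance = 1e-9)
  expect_equal(e$gain_ratio, 1, tolerance = 1e-9)
  expect_equal(e$phase_offset, 0, tolerance = 1e-9)
  expect_equal(e$axes, c(1, 1), tolerance = 1e-9)
})

test_that("imbalance parameters are recovered from the fitted ellipse", {
  iq <- gen_cw_iq(wide_displacement(), imbalance = std_imbalance(), snr_db = Inf)
  e <- fit_ellipse(iq)
  expect_equal(e$center, c(0.2, -0.1), tolerance = 1e-3)
  expect_equal(e$gain_ratio, 1.2, tolerance = 1e-3)
  expect_equal(e$phase_offset, 10 * pi / 180, tolerance = 1e-3)
})

test_that("five noiseless points determine the ellipse exactly", {
  th <- c(0.3, 1.1, 2.0, 3.4, 5.1)
  imb <- std_imbalance()
  pts <- cbind(imb$A_I * cos(th + imb$phi_I) + imb$B_I,
               imb$A_Q * sin(th + imb$phi_Q) + imb$B_Q)
  e <- fit_ellipse(pts)
  expect_equal(e$center, c(0.2, -0.1), tolerance = 1e-6)
  expect_equal(e$gain_ratio, 1.2, tolerance = 1e-6)
  expect_equal(e$phase_offset, 10 * pi / 180, tolerance = 1e-6)
})

test_that("degenerate point sets are rejected with a diagnostic", {
  x <- seq(0, 1, length.out = 20)
  expect_error(fit_ellipse(cbind(x, 2 * x + 1)), "degenerate|singular")
  expect_error(fit_ellipse(cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))), "5 distinct")
})

test_that("ellipse fitting is invariant to point order and equivariant to scale", {
  iq <- gen_cw_iq(wide_displacement(), imbalance = std_imbalance(), snr_db = Inf)
  pts <- cbind(iq$I, iq$Q)
  e1 <- fit_ellipse(pts)
  set.seed(5)
  e2 <- fit_ellipse(pts[sample(nrow(pts)), ])
  expect_equal(e2$center, e1$center, tolerance = 1e-9)
  expect_equal(e2$phase_offset, e1$phase_offset, tolerance = 1e-9)
  e3 <- fit_ellipse(3 * pts)
  expect_equal(e3$center, 3 * e1$center, tolerance = 1e-9)
  expect_equal(e3$axes, 3 * e1$axes, tolerance = 1e-8)
  expect_equal(e3$phase_offset, e1$phase_offset, tolerance = 1e-9)
  expect_equal(e3$gain_ratio, e1$gain_ratio, tolerance = 1e-9)
})

test_that("correction re-circularizes the I/Q cloud", {
  iq0 <- gen_cw_iq(wide_displacement(), snr_db = Inf)   # ideal sensor
  ident <- ellipse_params()
  out <- correct_iq(iq0, ident)
  expect_equal(out$I, iq0$I)
  expect_equal(out$Q, iq0$Q)
  iq <- gen_cw_iq(wide_displacement(), imbalance = std_imbalance(), snr_db = Inf)
  cc <- correct_iq(iq, fit_ellipse(iq))
  rad <- sqrt(cc$I^2 + cc$Q^2)
  expect_lt(stats::sd(rad) / mean(rad), 1e-3)
  # pure DC offset: correction is exactly the center shift
  iqdc <- gen_cw_iq(wide_displacement(), imbalance = cw_imbalance(B_I = 0.3, B_Q = -0.2),
                    snr_db = Inf)
  outdc <- correct_iq(iqdc, ellipse_params(center = c(0.3, -0.2)))
  expect_equal(outdc$I, iqdc$I - 0.3)
  expect_equal(outdc$Q, iqdc$Q + 0.2)
})

test_that("arctangent demodulation inverts the forward phase model", {
  lam <- 12.4e-3
  t <- (0:999) / 200
  r <- 1e-3 * sin(2 * pi * 0.3 * t)
  iq <- iq_record(cos(4 * pi * r / lam), sin(4 * pi * r / lam), fs = 200,
                  wavelength = lam)
  got <- arctangent_demodulate(iq)
  expect_lt(max(abs((got$samples - mean(got$samples)) - (r - mean(r)))), 1e-9)
  # constant I/Q gives a constant displacement
  cst <- arctangent_demodulate(iq_record(rep(0.6, 10), rep(0.8, 10), 10, lam))
  expect_equal(diff(cst$samples), rep(0, 9))
  expect_error(arctangent_demodulate(iq_record(c(1, 0), c(0, 0), 10, lam)),
               "zero-radius")
})

test_that("multi-wrap displacements are recovered after unwrapping", {
  lam <- carrier_wavelength(24.17)
  t <- (0:1999) / 200
  r <- sampled_signal(5e-3 * sin(2 * pi * 0.25 * t), ts = 1 / 200)  # 10 mm p-p
  iq <- gen_cw_iq(r, wavelength = lam, snr_db = Inf)
  got <- arctangent_demodulate(iq)
  err <- (got$samples - mean(got$samples)) - (r$samples - mean(r$samples))
  expect_lt(max(abs(err)), 1e-6)
})

test_that("fit-correct-demodulate inverts random imbalances to 0.1% RMS", {
  set.seed(31)
  for (i in 1:20) {
    imb <- cw_imbalance(B_I = runif(1, -0.5, 0.5), B_Q = runif(1, -0.5, 0.5),
                        A_I = runif(1, 0.5, 2), A_Q = 1,
                        phi_I = runif(1, -30, 30) * pi / 180, phi_Q = 0)
    t <- (0:1999) / 200
    r <- sampled_signal((1 + runif(1)) * 1e-3 * sin(2 * pi * runif(1, 0.2, 0.35) * t) +
                          4e-4 * sin(2 * pi * runif(1, 1, 1.5) * t + runif(1, 0, 2)),
                        ts = 1 / 200, unit = "m")
    iq <- gen_cw_iq(r, imbalance = imb, snr_db = Inf)
    got <- arctangent_demodulate(correct_iq(iq, fit_ellipse(iq)))
    ac_true <- r$samples - mean(r$samples)
    ac_got <- got$samples - mean(got$samples)
    expect_lt(rms(ac_got - ac_true) / rms(ac_true), 1e-3)
  }
})

test_that("the full CW front end feeds the pencil estimator", {
  t <- (0:7999) / 400
  r <- sampled_signal(2e-3 * sin(2 * pi * 0.3 * t) + 3e-4 * sin(2 * pi * 1.3 * t),
                      ts = 1 / 400, unit = "m")
  iq <- gen_cw_iq(r, imbalance = std_imbalance(), snr_db = Inf)
  disp <- cw_to_displacement(iq, fs_out = 50)
  expect_equal(1 / disp$ts, 50)
  v <- extract_vitals(disp, tol = 1e-6)
  expect_equal(v$f_b, 0.3, tolerance = 0.005)
  expect_equal(v$f_h, 1.3, tolerance = 0.005)
})
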