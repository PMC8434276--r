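test_that("Hankel matrix has the shifted structure", {
  H <- build_hankel(0:4, L = 2)
  expect_equal(H, matrix(c(0, 1, 2, 1, 2, 3, 2, 3, 4), nrow = 3))
  expect_equal(dim(build_hankel(rnorm(12), L = 4)), c(8, 5))
  expect_error(build_hankel(rnorm(10), L = 10), "0 < L < N")
  expect_error(build_hankel(rnorm(10), L = 0), "0 < L < N")
})

test_that("model order counts singular values above the ratio threshold", {
  expect_identical(estimate_model_order(c(1, 0.5, 1e-6), 1e-4), 2L)
  # a noise floor at 1e-4: values at/below the ratio are discarded
  expect_identical(estimate_model_order(c(1, 3e-4, 9e-5), 1e-4), 2L)
  expect_identical(estimate_model_order(c(0, 0, 0), 0.5), 0L)
  # equality with the threshold discards
  expect_identical(estimate_model_order(c(1, 1e-4), 1e-4), 1L)
  expect_error(estimate_model_order(c(1, -0.1), 1e-4), "nonnegative")
  expect_error(estimate_model_order(c(0.5, 1), 1e-4), "descending")
  expect_error(estimate_model_order(c(1, 0.5), 2), "tol")
})

test_that("a noiseless cosine is recovered exactly as one conjugate pair", {
  t <- (0:499) * 0.02
  fit <- mpm(cos(2 * pi * 1.0 * t), ts = 0.02, tol = 1e-8)
  expect_model_invariants(fit)
  expect_equal(nrow(fit$poles), 2L)
  expect_equal(sort(fit$poles$f), c(-1, 1), tolerance = 1e-8)
  expect_equal(fit$poles$damping, c(0, 0), tolerance = 1e-8)
  expect_equal(Mod(fit$poles$residue), c(0.5, 0.5), tolerance = 1e-8)
  expect_lt(rms(residuals(fit)) / rms(fit$y), 1e-8)
})

test_that("two damped components are recovered to 1e-6 in all parameters", {
  params <- data.frame(f = c(0.3, 1.2), alpha = c(-0.2, -0.1),
                       amp = c(1.0, 0.25), phase = c(0, 0.7))
  y <- synth_damped_sum(params, n = 1000, ts = 0.02)
  fit <- mpm(y, ts = 0.02, tol = 1e-8)
  expect_model_invariants(fit)
  expect_equal(nrow(fit$poles), 4L)
  got <- match_poles(fit, params$f)
  expect_equal(got$f, params$f, tolerance = 1e-6)
  expect_equal(got$alpha, params$alpha, tolerance = 1e-6)
  expect_equal(got$amp, params$amp, tolerance = 1e-6)
  expect_equal(got$phase, params$phase, tolerance = 1e-6)
})

test_that("random noiseless sums of up to 6 damped sinusoids are recovered exactly", {
  set.seed(42)
  for (i in 1:15) {
    M <- sample(1:6, 1)
    params <- rand_params(M)
    y <- synth_damped_sum(params, n = 600, ts = 0.02)
    fit <- mpm(y, ts = 0.02, tol = 1e-9)
    expect_model_invariants(fit)
    got <- match_poles(fit, params$f)
    expect_equal(got$f, params$f, tolerance = 1e-6)
    expect_equal(got$alpha, params$alpha, tolerance = 1e-6)
    expect_equal(got$amp, params$amp, tolerance = 1e-6)
  }
})

test_that("degenerate inputs are handled", {
  expect_error(mpm(c(1, NA, 3, 4), ts = 0.1), "finite")
  z <- mpm(rep(0, 50), ts = 0.1)
  expect_identical(nrow(z$poles), 0L)
  expect_equal(reconstruct(z, integer(0), n = 10)$samples, rep(0, 10))
  expect_error(mpm(rnorm(3), ts = 0.1), "at least 4")
})

test_that("reconstruction round-trips, selects components, and checks closure", {
  params <- data.frame(f = c(0.3, 1.2), alpha = c(-0.2, -0.1),
                       amp = c(1.0, 0.25), phase = c(0, 0.7))
  y <- synth_damped_sum(params, n = 1000, ts = 0.02)
  fit <- mpm(y, ts = 0.02, tol = 1e-8)
  expect_lt(rms(reconstruct(fit)$samples - y) / rms(y), 1e-8)
  # select only the 1.2 Hz pair: matches forward synthesis of that component
  pair <- which(abs(abs(fit$poles$f) - 1.2) < 0.05)
  comp <- synth_damped_sum(params[2, ], n = 1000, ts = 0.02)
  expect_lt(rms(reconstruct(fit, pair)$samples - comp) / rms(comp), 1e-6)
  # a half-open selection is rejected
  one <- which(fit$poles$f == max(fit$poles$f))[1]
  expect_error(reconstruct(fit, one), "conjugation")
  expect_equal(reconstruct(fit, integer(0))$samples, rep(0, 1000))
})

test_that("delaying the signal leaves poles fixed and scales residues by z^-d", {
  set.seed(7)
  params <- rand_params(3)
  d <- 25
  y_full <- synth_damped_sum(params, n = 700 + d, ts = 0.02)
  f0 <- mpm(y_full[1:700], ts = 0.02, tol = 1e-9)
  f1 <- mpm(y_full[(d + 1):(d + 700)], ts = 0.02, tol = 1e-9)
  p0 <- f0$poles[order(f0$poles$f), ]
  p1 <- f1$poles[order(f1$poles$f), ]
  expect_equal(p1$f, p0$f, tolerance = 1e-7)
  expect_equal(p1$damping, p0$damping, tolerance = 1e-6)
  expect_equal(p1$residue, p0$residue * p0$z^d, tolerance = 1e-5)
})

test_that("reconstruction residual does not grow as tol decreases", {
  set.seed(11)
  params <- rand_params(4)
  y <- synth_damped_sum(params, n = 600, ts = 0.02)
  tols <- 10^(-(1:8))
  res <- vapply(tols, function(tl) {
    fit <- mpm(y, ts = 0.02, tol = tl)
    if (!nrow(fit$poles)) return(1)
    rms(residuals(fit)) / rms(y)
  }, 0)
  expect_true(all(diff(res) <= 1e-9))
})

test_that("segmentation produces the documented window layout", {
  y <- sampled_signal(rnorm(2750), ts = 0.02)          # 55 s at 50 Hz
  w <- segment_signal(y, 12.5)
  expect_length(w, 4L)
  expect_true(all(vapply(w, function(x) length(x$samples), 0L) == 625L))
  w1 <- segment_signal(y, 55)
  expect_length(w1, 1L)
  expect_equal(w1[[1]]$samples, y$samples)
  y2 <- sampled_signal(rnorm(3000), ts = 0.02)         # 60 s at 50 Hz
  w2 <- segment_signal(y2, 20, overlap_fraction = 0.5)
  expect_length(w2, 5L)
  expect_equal(vapply(w2, function(x) x$t0, 0), c(0, 10, 20, 30, 40))
  expect_error(segment_signal(y, 100), "longer than signal")
  expect_error(segment_signal(y, 12.5, 1), "overlap")
})

test_that("pole tables round-trip through the delimited serialization", {
  t <- (0:499) * 0.02
  fit <- mpm(cos(2 * pi * 1.0 * t) + 0.5 * cos(2 * pi * 2.4 * t), ts = 0.02,
             tol = 1e-8)
  path <- tempfile(fileext = ".tsv")
  write_poles(fit, path)
  back <- read_poles(path, ts = 0.02, n = 500)
  expect_equal(back$poles$f, fit$poles$f, tolerance = 1e-12)
  expect_equal(back$poles$residue, fit$poles$residue, tolerance = 1e-12)
  expect_lt(rms(reconstruct(back)$samples - reconstruct(fit)$samples) /
              rms(fit$y), 1e-10)
})

test_that("fitted model methods are coherent", {
  t <- (0:499) * 0.02
  y <- cos(2 * pi * 0.7 * t)
  fit <- mpm(y, ts = 0.02, tol = 1e-8)
  expect_s3_class(coef(fit), "data.frame")
  expect_equal(fitted(fit) + residuals(fit), y)
  expect_equal(predict(fit, n = 100)$samples, fitted(fit)[1:100], tolerance = 1e-9)
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sim, 2L)
  expect_length(sim[[1]]$samples, 500L)
  expect_output(print(fit), "Matrix pencil fit")
  expect_output(print(summary(fit)), "residual")
})
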