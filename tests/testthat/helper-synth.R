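# shared fixtures: random damped-sinusoid sums with known parameters, and
# invariant checks applied to every matrix pencil fit in the suite

# y(t) = sum_m amp_m e^(alpha_m t) cos(2 pi f_m t + phase_m)
synth_damped_sum <- function(params, n, ts) {
  t <- (seq_len(n) - 1) * ts
  y <- rep(0, n)
  for (m in seq_len(nrow(params)))
    y <- y + params$amp[m] * exp(params$alpha[m] * t) *
      cos(2 * pi * params$f[m] * t + params$phase[m])
  y
}

# draw M components with well-separated frequencies and mild decay
rand_params <- function(M, f_range = c(0.2, 20), min_sep = 0.35) {
  repeat {
    f <- sort(runif(M, f_range[1], f_range[2]))
    if (M == 1 || min(diff(f)) >= min_sep) break
  }
  data.frame(f = f,
             alpha = runif(M, -0.2, 0),
             amp = runif(M, 0.2, 2),
             phase = runif(M, -pi, pi))
}

# recovered (f, alpha, |R|, arg R) for the positive-frequency poles, matched
# to true frequencies
match_poles <- function(fit, true_f) {
  pos <- which(fit$poles$f > 0)
  idx <- vapply(true_f, function(f0) pos[which.min(abs(fit$poles$f[pos] - f0))], 0L)
  data.frame(f = fit$poles$f[idx],
             alpha = fit$poles$damping[idx],
             amp = 2 * Mod(fit$poles$residue[idx]),   # pair amplitude
             phase = Arg(fit$poles$residue[idx]))
}

# conjugate symmetry + real reconstruction + reconstruction additivity,
# asserted on every decomposition the suite produces
expect_model_invariants <- function(fit) {
  p <- fit$poles
  if (!nrow(p)) return(invisible(fit))
  # pole multiset invariant under conjugation
  csort <- function(z) z[order(Re(z), Im(z))]
  expect_equal(csort(p$z), csort(Conj(p$z)), tolerance = 1e-9)
  # recorded partners are mutual
  for (i in seq_len(nrow(p))) {
    j <- p$conj[i]
    if (!is.na(j)) expect_identical(p$conj[j], i)
  }
  # full reconstruction is real (warning-free) and additive over a partition
  full <- reconstruct(fit)
  expect_true(all(is.finite(full$samples)))
  half <- which(abs(p$f) <= stats::median(abs(p$f)))
  half <- sort(unique(c(half, p$conj[half][!is.na(p$conj[half])])))
  rest <- setdiff(seq_len(nrow(p)), half)
  add <- reconstruct(fit, half)$samples + reconstruct(fit, rest)$samples
  scale <- max(rms(full$samples), 1e-12)
  expect_lt(rms(add - full$samples) / scale, 1e-9)
  invisible(fit)
}

rms <- function(x) sqrt(mean(x^2))

# hand-built pole models for post-processing tests: undamped conjugate pairs
# at the given frequencies with the given pair amplitudes
make_pole_model <- function(f, amp, ts = 0.02, n = 1000, damping = 0) {
  damping <- rep_len(damping, length(f))
  s <- complex(real = damping, imaginary = 2 * pi * f)
  s <- c(s, Conj(s))
  R <- complex(modulus = rep(amp / 2, 2), argument = rep(0, 2 * length(f)))
  ord <- order(abs(Im(s)), Im(s))
  s <- s[ord]; R <- R[ord]
  poles <- data.frame(f = Im(s) / (2 * pi), damping = Re(s))
  poles$residue <- R
  poles$z <- exp(s * ts)
  poles$conj <- vitalpencil:::conj_partners(poles$z)
  structure(list(poles = poles, Ts = ts, N = n, t0 = 0, tol = 1e-4,
                 L = floor(n / 3), y = rep(NA_real_, n)),
            class = "mpm")
}
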