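#' Hankel data matrix for the matrix pencil
#'
#' Builds the `(N - L) x (L + 1)` Hankel matrix whose element `(i, j)` is
#' `y[i + j]` (0-based). Deleting its last column gives `Y1` and deleting its
#' first column gives `Y2`, the shifted pair whose pencil eigenvalues are the
#' signal poles.
#'
#' @param y a [sampled_signal()] or numeric vector.
#' @param L pencil parameter, `0 < L < N`; `N/3 <= L <= N/2` gives the best
#'   noise filtering.
#' @return numeric matrix of dimension `(N - L) x (L + 1)`.
#' @examples
#' build_hankel(0:4, L = 2)
#' @export
build_hankel <- function(y, L) {
  x <- if (inherits(y, "sampled_signal")) y$samples else as.numeric(y)
  n <- length(x)
  if (length(L) != 1L || !is.finite(L) || L != round(L))
    stop("'L' must be a single integer")
  if (L <= 0 || L >= n) stop("'L' must satisfy 0 < L < N")
  idx <- outer(0:(n - L - 1L), 0:L, `+`) + 1L
  matrix(x[idx], nrow = n - L, ncol = L + 1L)
}

#' Model order from a singular-value ratio threshold
#'
#' The number of damped exponentials `M` is the count of singular values whose
#' ratio to the largest exceeds `tol`; everything at or below the threshold is
#' treated as noise. `tol` reflects the sensor's noise floor: data reported to
#' four significant digits imply `tol = 1e-4`, which is also the measured
#' noise variance of the UWB device this pipeline targets.
#'
#' @param singular_values nonnegative values sorted in descending order.
#' @param tol ratio threshold in `(0, 1)`; strictly greater-than keeps a value.
#' @return integer model order `M` (0 for an all-zero spectrum).
#' @examples
#' estimate_model_order(c(1, 0.5, 1e-6), tol = 1e-4)  # 2
#' @export
estimate_model_order <- function(singular_values, tol) {
  sv <- as.numeric(singular_values)
  if (any(!is.finite(sv)) || any(sv < 0)) stop("singular values must be finite and nonnegative")
  if (any(diff(sv) > 0)) stop("singular values must be sorted descending")
  if (length(tol) != 1L || !is.finite(tol) || tol <= 0 || tol >= 1)
    stop("'tol' must be in (0, 1)")
  if (length(sv) == 0L || sv[1] == 0) return(0L)
  sum(sv / sv[1] > tol)
}

#' Fit a damped complex-exponential model by the matrix pencil method
#'
#' Models a real sampled signal as `y(k Ts) ~ sum_i R_i z_i^k` with
#' `z_i = exp(s_i Ts)`, `s_i = alpha_i + j 2 pi f_i`. The poles `z_i` are the
#' generalized eigenvalues of the shifted Hankel pair `{Y2 - lambda Y1}`,
#' computed through the truncated-SVD pseudo-inverse route: the SVD of the
#' Hankel matrix is thresholded at `tol` to pick the model order `M`, and the
#' eigenvalues of `pinv(V1s) V2s` in the `M`-dimensional filtered subspace
#' give the `z_i`. Natural frequencies are recovered on the principal branch,
#' `s_i = log(z_i) / Ts`, and the residues `R_i` solve the Vandermonde
#' least-squares system by a rank-revealing SVD solve.
#'
#' Poles of a real signal come in conjugate pairs; the fit symmetrizes each
#' pair so the pairing is exact, and records each pole's partner. Eigenvalues
#' with `|z| < zmin` or implying growth faster than `alpha_max` (unphysical
#' for vital signs) are discarded.
#'
#' @param y a [sampled_signal()], or numeric vector with `ts` supplied.
#' @param tol singular-value ratio threshold in `(0, 1)`; default `1e-4`, the
#'   noise floor of 4-significant-digit sensor data.
#' @param L pencil parameter; default `floor(N/3)`, the cheap end of the
#'   recommended `N/3 < L < N/2` band.
#' @param ts sampling interval in seconds when `y` is a plain vector.
#' @param alpha_max largest admissible growth rate in 1/s.
#' @param zmin smallest admissible `|z|` (the log is undefined at 0).
#' @return An object of class `"mpm"`: a list with
#'   \item{poles}{data frame with columns `f` (Hz), `damping` (1/s, negative
#'     decays), `residue` (complex), `z` (complex discrete pole), `conj` (row
#'     index of the conjugate partner, `NA` if none).}
#'   \item{Ts, N, t0}{sampling metadata of the fitted window.}
#'   \item{tol, L}{settings used.}
#'   \item{y}{the fitted samples (for `fitted()`/`residuals()`).}
#' @examples
#' t <- seq(0, by = 0.02, length.out = 500)
#' fit <- mpm(cos(2 * pi * 1.0 * t), ts = 0.02, tol = 1e-8)
#' coef(fit)   # conjugate pair at +-1 Hz, |R| = 0.5
#' @seealso [reconstruct()], [extract_vitals()], [find_breathing()]
#' @export
mpm <- function(y, tol = 1e-4, L = NULL, ts = NULL, alpha_max = 50, zmin = 1e-12) {
  y <- as_sampled_signal(y, ts = ts)
  x <- y$samples
  n <- length(x)
  if (n < 4L) stop("matrix pencil fit needs at least 4 samples")
  if (all(x == 0)) return(empty_mpm(y, tol, if (is.null(L)) floor(n / 3) else L))
  if (is.null(L)) L <- floor(n / 3)
  H <- build_hankel(x, L)
  sv <- svd(H)
  M <- estimate_model_order(sv$d, tol)
  M <- min(M, L, n - L)
  if (M == 0L) return(empty_mpm(y, tol, L))
  Vs <- sv$v[, seq_len(M), drop = FALSE]         # (L+1) x M
  V1 <- Vs[-(L + 1L), , drop = FALSE]
  V2 <- Vs[-1L, , drop = FALSE]
  A <- solve(crossprod(V1), crossprod(V1, V2))   # pinv(V1) V2, M x M
  z <- eigen(A, only.values = TRUE)$values
  if (is.numeric(z)) z <- complex(real = z, imaginary = 0)
  # growth cap: alpha_max physically, and |z|^N must stay representable
  zmax <- min(exp(alpha_max * y$ts), 10^(290 / n))
  keep <- Mod(z) > zmin & Mod(z) <= zmax
  z <- z[keep]
  if (length(z) == 0L) return(empty_mpm(y, tol, L))
  z <- pair_conjugates(z)
  s <- log(z) / y$ts
  # residues: least squares on the N x M Vandermonde system; columns are
  # equilibrated to unit norm first (exact reparametrization) so a single
  # fast-growing pole cannot swamp the rank tolerance of the solve
  Z <- exp(outer(0:(n - 1L), log(z)))
  cn <- sqrt(colSums(Mod(Z)^2))
  R <- svd_lstsq(sweep(Z, 2, cn, "/"), x) / cn
  R <- symmetrize_residues(z, R)
  ord <- order(abs(Im(s)), Im(s), Re(s))
  z <- z[ord]; s <- s[ord]; R <- R[ord]
  poles <- data.frame(f = Im(s) / (2 * pi), damping = Re(s))
  poles$residue <- R
  poles$z <- z
  poles$conj <- conj_partners(z)
  structure(list(poles = poles, Ts = y$ts, N = n, t0 = y$t0, tol = tol, L = L,
                 y = x),
            class = "mpm")
}

empty_mpm <- function(y, tol, L) {
  poles <- data.frame(f = numeric(0), damping = numeric(0))
  poles$residue <- complex(0)
  poles$z <- complex(0)
  poles$conj <- integer(0)
  structure(list(poles = poles, Ts = y$ts, N = length(y$samples), t0 = y$t0,
                 tol = tol, L = L, y = y$samples),
            class = "mpm")
}

# complex least squares via SVD with relative rank tolerance
svd_lstsq <- function(A, b, rcond = 1e-12) {
  sv <- La.svd(A)
  d <- sv$d
  pos <- d > max(d) * rcond
  ut_b <- Conj(t(sv$u[, pos, drop = FALSE])) %*% b
  drop(Conj(t(sv$vt[pos, , drop = FALSE])) %*% (ut_b / d[pos]))
}

# eigenvalues of a real matrix are exactly conjugate-paired; snap near-real
# ones to the axis and average each pair so symmetry is exact
pair_conjugates <- function(z, tol = 1e-9) {
  scale <- max(Mod(z))
  near_real <- abs(Im(z)) <= tol * scale
  z[near_real] <- complex(real = Re(z[near_real]), imaginary = 0)
  pos <- which(Im(z) > 0)
  neg <- which(Im(z) < 0)
  used <- rep(FALSE, length(neg))
  for (i in pos) {
    if (!length(neg)) break
    d <- Mod(z[neg] - Conj(z[i]))
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= 1e-6 * scale + 1e-12) {
      m <- (z[i] + Conj(z[neg[j]])) / 2
      z[i] <- m
      z[neg[j]] <- Conj(m)
      used[j] <- TRUE
    }
  }
  z
}

conj_partners <- function(z, tol = 1e-9) {
  n <- length(z)
  out <- rep(NA_integer_, n)
  scale <- max(Mod(z), 1e-300)
  for (i in seq_len(n)) {
    if (Im(z[i]) == 0) { out[i] <- i; next }
    j <- which(z == Conj(z[i]))
    j <- setdiff(j, i)
    if (length(j)) out[i] <- j[1]
  }
  out
}

symmetrize_residues <- function(z, R) {
  prt <- conj_partners(z)
  for (i in seq_along(z)) {
    j <- prt[i]
    if (is.na(j)) next
    if (j == i) { R[i] <- complex(real = Re(R[i]), imaginary = 0); next }
    if (j > i) {
      m <- (R[i] + Conj(R[j])) / 2
      R[i] <- m
      R[j] <- Conj(m)
    }
  }
  R
}

#' Reconstruct a signal from selected poles
#'
#' Evaluates `y_k = sum_i R_i z_i^k` over the selected poles. The selection
#' must be closed under conjugation (a pole's partner must be selected with
#' it) so the sum is real; the imaginary residual is checked against
#' `1e-9 * RMS` and the real part returned.
#'
#' @param model an [mpm()] fit.
#' @param indices integer rows of `model$poles` to keep; default all.
#' @param n number of samples to synthesize; default the fitted length.
#' @return a [sampled_signal()].
#' @export
reconstruct <- function(model, indices = NULL, n = NULL) {
  stopifnot(inherits(model, "mpm"))
  if (is.null(n)) n <- model$N
  if (is.null(indices)) indices <- seq_len(nrow(model$poles))
  indices <- as.integer(indices)
  if (length(indices) == 0L)
    return(sampled_signal(rep(0, n), ts = model$Ts, t0 = model$t0))
  if (any(indices < 1L | indices > nrow(model$poles)))
    stop("pole index out of range")
  prt <- model$poles$conj[indices]
  if (any(!is.na(prt) & !(prt %in% indices)))
    stop("pole selection is not closed under conjugation")
  z <- model$poles$z[indices]
  R <- model$poles$residue[indices]
  out <- exp(outer(0:(n - 1L), log(z))) %*% R
  out <- drop(out)
  s_rms <- sqrt(mean(Mod(out)^2))
  if (s_rms > 0 && max(abs(Im(out))) > 1e-9 * s_rms)
    warning("non-negligible imaginary residual in reconstruction")
  sampled_signal(Re(out), ts = model$Ts, t0 = model$t0)
}
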