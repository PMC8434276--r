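#' Strength of each pole over the fitted window
#'
#' A pole's strength is the RMS of its contribution `|R| e^(alpha t)` over the
#' analysis window: equal to `|R|` for an undamped pole and
#' `|R| sqrt((e^(2 alpha T) - 1) / (2 alpha T))` otherwise. Breathing and
#' heartbeat candidates are ranked by this quantity ("energy" and "amplitude"
#' coincide for near-zero damping).
#'
#' @param model an [mpm()] fit.
#' @return numeric vector, one strength per pole row.
#' @export
pole_strength <- function(model) {
  stopifnot(inherits(model, "mpm"))
  a <- model$poles$damping
  T <- model$N * model$Ts
  amp <- Mod(model$poles$residue)
  fac <- ifelse(abs(a) * T < 1e-8, 1, sqrt(pmax(expm1(2 * a * T), -1 + 1e-300) / (2 * a * T)))
  amp * fac
}

# |f - k f0| <= max(abs_tol, rel_tol * k * f0)
harmonic_tol <- function(k, f0, abs_tol = 0.05, rel_tol = 0.04) {
  pmax(abs_tol, rel_tol * k * f0)
}

# a vital-sign pole persists across the window: poles whose amplitude changes
# by more than nepers_max nepers over the fitted window are boundary/noise
# artifacts and take no part in selection or family membership
quasi_stationary <- function(model, nepers_max = 10) {
  abs(model$poles$damping) * (model$N * model$Ts) <= nepers_max
}

# rows (with f > 0) within tolerance of k*f0 for k in ks
harmonic_members <- function(model, f0, ks, abs_tol = 0.05, rel_tol = 0.04) {
  f <- model$poles$f
  ok <- quasi_stationary(model)
  hit <- rep(FALSE, length(f))
  for (k in ks)
    hit <- hit | (f > 0 & ok &
                    abs(f - k * f0) <= harmonic_tol(k, f0, abs_tol, rel_tol))
  which(hit)
}

close_under_conjugation <- function(model, idx) {
  prt <- model$poles$conj[idx]
  sort(unique(c(idx, prt[!is.na(prt)])))
}

#' Locate the breathing pole and its harmonic family
#'
#' The breathing rate is the frequency of the strongest pole inside the
#' breathing band (0.1-0.4 Hz for resting adults; raise the upper edge to
#' 0.8 Hz for exercise or infants). Candidates whose second or third harmonic
#' is also present among the poles are preferred (breathing harmonics are a
#' hallmark of real chest displacement); if no candidate has one, the
#' strongest candidate is taken. The family is the fundamental plus every
#' pole within tolerance of `k * f_b`, `k <= n_harmonics`, closed under
#' conjugation.
#'
#' @param model an [mpm()] fit.
#' @param band numeric length-2 breathing band in Hz.
#' @param n_harmonics highest harmonic index included in the family.
#' @param harmonic_check prefer candidates with a detected 2nd/3rd harmonic.
#' @param abs_tol,rel_tol harmonic matching tolerance:
#'   `|f - k f0| <= max(abs_tol, rel_tol * k * f0)`.
#' @return list with `f_b` (Hz, `NA` if no pole lies in the band), `indices`
#'   (integer pole rows, empty if none), and `found` (logical).
#' @export
find_breathing <- function(model, band = c(0.1, 0.4), n_harmonics = 4,
                           harmonic_check = TRUE, abs_tol = 0.05, rel_tol = 0.04) {
  stopifnot(inherits(model, "mpm"), length(band) == 2L)
  sel <- select_fundamental(model, band, harmonic_check, abs_tol, rel_tol)
  if (is.na(sel))
    return(list(f_b = NA_real_, indices = integer(0), found = FALSE))
  f_b <- model$poles$f[sel]
  fam <- union(sel, harmonic_members(model, f_b, seq_len(n_harmonics), abs_tol, rel_tol))
  fam <- close_under_conjugation(model, fam)
  list(f_b = f_b, indices = fam, found = TRUE)
}

#' Locate the heartbeat pole and its harmonic family
#'
#' After the breathing family has been removed, the heartbeat is the
#' strongest pole in the heart band (0.8-2 Hz at rest; 1-2.2 Hz under
#' exercise). Usually only the first four harmonics carry enough SNR, so the
#' family is the fundamental plus poles within tolerance of `k * f_h`,
#' `k <= n_harmonics`. An optional harmonic-presence check skips a candidate
#' lacking any detected harmonic in favor of the next-strongest candidate
#' that has one (the disambiguation used when a residual breathing harmonic
#' outweighs the true heartbeat).
#'
#' @inheritParams find_breathing
#' @param band numeric length-2 heart band in Hz.
#' @param harmonic_check enable the harmonic-presence disambiguation
#'   (off by default: after breathing removal the strongest in-band pole is
#'   the heartbeat).
#' @return list with `f_h`, `indices`, `found` as in [find_breathing()].
#' @export
find_heartbeat <- function(model, band = c(0.8, 2), n_harmonics = 4,
                           harmonic_check = FALSE, abs_tol = 0.05, rel_tol = 0.04) {
  stopifnot(inherits(model, "mpm"), length(band) == 2L)
  sel <- select_fundamental(model, band, harmonic_check, abs_tol, rel_tol)
  if (is.na(sel))
    return(list(f_h = NA_real_, indices = integer(0), found = FALSE))
  f_h <- model$poles$f[sel]
  fam <- union(sel, harmonic_members(model, f_h, 2:n_harmonics, abs_tol, rel_tol))
  fam <- close_under_conjugation(model, fam)
  list(f_h = f_h, indices = fam, found = TRUE)
}

# strongest in-band positive-frequency pole, optionally preferring candidates
# with a detected harmonic; ties broken toward lower frequency. Candidates
# weaker than 1% of the model's strongest pole are noise, not vital signs.
select_fundamental <- function(model, band, harmonic_check, abs_tol, rel_tol,
                               strength_floor = 0.01) {
  f <- model$poles$f
  ok <- quasi_stationary(model)
  st_all <- pole_strength(model)
  st_ref <- max(st_all[ok], 0)
  cand <- which(f >= band[1] & f <= band[2] & ok &
                  st_all >= strength_floor * st_ref)
  if (!length(cand)) return(NA_integer_)
  st <- st_all[cand]
  ord <- cand[order(-st, f[cand])]
  if (harmonic_check) {
    for (i in ord) {
      others <- setdiff(seq_along(f), close_under_conjugation(model, i))
      for (k in 2:3) {
        hit <- abs(f[others] - k * f[i]) <= harmonic_tol(k, f[i], abs_tol, rel_tol) &
          f[others] > 0
        if (any(hit)) return(i)
      }
    }
  }
  ord[1]
}

#' Remove a pole family from a model
#'
#' Returns the model without exactly the given pole rows; all other poles are
#' untouched. Used to subtract the breathing family before heartbeat search.
#'
#' @param model an [mpm()] fit.
#' @param indices pole rows to drop, closed under conjugation.
#' @return an [mpm()] object without those poles.
#' @export
remove_family <- function(model, indices) {
  stopifnot(inherits(model, "mpm"))
  indices <- as.integer(indices)
  if (!length(indices)) return(model)
  if (any(indices < 1L | indices > nrow(model$poles))) stop("pole index out of range")
  prt <- model$poles$conj[indices]
  if (any(!is.na(prt) & !(prt %in% indices)))
    stop("pole selection is not closed under conjugation")
  keep_model(model, setdiff(seq_len(nrow(model$poles)), indices))
}

#' Keep only poles inside a frequency band
#'
#' Retains conjugate pairs whose `|f|` lies in the band (default 0.8-10 Hz,
#' the post-breathing band in which heartbeat harmonics live) and discards
#' the rest.
#'
#' @param model an [mpm()] fit.
#' @param band numeric length-2 band in Hz applied to `|f|`.
#' @return an [mpm()] object.
#' @export
band_retain <- function(model, band = c(0.8, 10)) {
  stopifnot(inherits(model, "mpm"), length(band) == 2L)
  keep <- which(abs(model$poles$f) >= band[1] & abs(model$poles$f) <= band[2])
  keep_model(model, close_under_conjugation(model, keep))
}

# subset the pole table, remapping conjugate partner indices
keep_model <- function(model, keep) {
  keep <- sort(unique(as.integer(keep)))
  p <- model$poles[keep, , drop = FALSE]
  remap <- match(model$poles$conj[keep], keep)
  p$conj <- remap
  rownames(p) <- NULL
  model$poles <- p
  model
}
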