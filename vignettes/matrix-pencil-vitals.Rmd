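---
title: "Pole-domain vital-sign extraction: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pole-domain vital-sign extraction: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

A microwave sensor observing a breathing person with a beating heart
measures a displacement signal that is, over an analysis window, well
approximated by a sum of damped complex exponentials:

$$y(kT_s) \approx \sum_{i=1}^{M} R_i z_i^k, \qquad
  z_i = e^{s_i T_s},\quad s_i = \alpha_i + j2\pi f_i .$$

Every physiologically meaningful component — breathing and its harmonics,
the heartbeat and its harmonics — corresponds to a conjugate pole pair
$(z_i, \bar z_i)$ with frequency $f_i$, damping $\alpha_i$ (negative for a
decaying component) and complex amplitude (residue) $R_i$. Unlike Fourier
analysis, this parametric model has no resolution limit tied to the window
length, and unlike autoregressive models it handles transient
(non-stationary) components naturally: anything that fits a damped
exponential is representable.

`mpm()` estimates the model with the matrix pencil method:

1. Build the $(N-L)\times(L+1)$ Hankel matrix of the samples. The pencil
   parameter $L$ trades noise filtering against identifiability; we default
   to $L=\lfloor N/3\rfloor$, the cheap end of the recommended
   $N/3 < L < N/2$ band (smallest SVD cost inside it).
2. SVD-truncate: the model order $M$ is the number of singular values with
   $\sigma_i/\sigma_1 > \mathrm{tol}$ (strict inequality — a value at the
   threshold is noise). `tol` encodes the sensor's noise floor: data
   quoted to four significant digits imply `tol = 1e-4` (the default);
   at 15–20 dB broadband SNR, noise singular values sit near 1% of
   $\sigma_1$ and `tol = 1e-2` is the matched choice.
3. The poles are the eigenvalues of $\mathrm{pinv}(V_{1s})\,V_{2s}$, where
   $V_{1s}, V_{2s}$ are the truncated right-singular-vector matrix with the
   last/first row deleted — the standard reduced form of the generalized
   eigenvalue problem $\{Y_2 - \lambda Y_1\}$, numerically equivalent to
   the pseudo-inverse route $Y_1^{+}Y_2$ in the filtered subspace.
4. Frequencies and dampings come from the principal branch of the
   logarithm, $s_i = \ln(z_i)/T_s$. A printed form that reads the
   frequency directly from $\mathrm{Im}\,\lambda_i$ is dimensionally
   inconsistent with $z_i = e^{s_i T_s}$; the logarithm is the consistent
   reading and what we implement. The sign convention is fixed by storing
   $\alpha_i = \mathrm{Re}\ln(z_i)/T_s$ unchanged (negative = decaying).
5. Residues solve the Vandermonde least-squares system. We replace the
   printed normal-equations form with an SVD-based solve (identical
   solution, numerically stable) after scaling every Vandermonde column to
   unit norm — an exact reparametrization without which a single
   slowly-growing noise pole dominates the rank tolerance and silently
   zeroes every other residue.

Eigenvalues of a real data matrix come in exact conjugate pairs; the fit
symmetrizes each pair and records the partner index, so conjugate-closed
pole selections reconstruct strictly real signals. Sanitation discards
$|z_i| < 10^{-12}$ (the log is undefined at zero) and growth faster than
$\alpha_{\max} = 50\,\mathrm{s}^{-1}$, additionally capped so $|z|^N$ stays
representable in double precision.

# Pole post-processing

Separation happens in the pole domain (`find_breathing()`,
`remove_family()`, `band_retain()`, `find_heartbeat()`, composed by
`extract_vitals()`):

* **Breathing**: strongest pole in 0.1–0.4 Hz (12–24 breaths/min at rest;
  widen to 0.8 Hz for exercise or infants). Candidates whose 2nd or 3rd
  harmonic is also present are preferred; if none has one, the strongest
  candidate is taken — a single clean pole in the band still counts as
  breathing. The family is the fundamental plus every pole within the
  harmonic tolerance of $k f_b$, $k \le 4$.
* **Family removal and band retention**: the breathing family is removed
  outright and only 0.8–10 Hz poles are kept.
* **Heartbeat**: strongest remaining pole in 0.8–2 Hz (1–2.2 Hz under
  exercise), plus its first four harmonics (higher harmonics rarely carry
  usable SNR at a 50 Hz sampling rate). An optional harmonic-presence
  check (off by default; the strongest in-band pole after breathing
  removal is normally the heartbeat) skips a candidate lacking any
  detected harmonic.
* **Reconstruction**: respiration = breathing family; artery pulsation =
  heartbeat family.

The essential robustness property: a breathing harmonic *inside* the heart
band is removed because its frequency is a multiple of $f_b$ — its
amplitude is irrelevant. Band-pass extraction, which keeps whatever is
strongest in the band, fails exactly there.

Three numerical rules the literature leaves open, fixed here:

* **Harmonic matching tolerance**: $|f - kf_0| \le \max(0.05\,\mathrm{Hz},
  0.04\,k f_0)$ — an absolute floor absorbing pole jitter at low
  frequencies, a proportional term tracking error growth at higher
  harmonics. Configurable.
* **Pole strength**: the RMS of $|R_i|e^{\alpha_i t}$ over the window
  ($=|R_i|$ for an undamped pole), so "energy" and "amplitude" rankings
  coincide where they should.
* **Selection validity**: a candidate (or family member) must be
  quasi-stationary — its amplitude may change by at most $e^{10}$ over the
  window ($|\alpha_i| N T_s \le 10$) — and no weaker than 1% of the
  model's strongest quasi-stationary pole. Without these guards,
  boundary-transient poles with large positive damping, whose window RMS is
  huge but which represent no sustained oscillation, win the argmax.
  Ties break toward lower frequency.

# Window sizing

The minimum window is five cycles of the slowest component of interest:
12.5–20 s when breathing down to 0.25 Hz must be resolved. Long windows
help only while the signal is stationary; beat-interval jitter diffuses the
heartbeat phase, so beyond ~30 s the heart line smears across several
poles. For tracking a *changing* rate (the after-exercise scenario) we use
8 s windows with 50% overlap: ≥ 9 heart cycles per window, locally
near-constant rate, and a still-identifiable breathing pole (breathing is
strong enough to be found with ~2.5 cycles). Overlapping windows are
joined by weighted overlap-add with linear cross-fades; plain concatenation
leaves stitch discontinuities that beat detection mistakes for peaks.

# Sensor front ends

**CW (Doppler)**: the quadrature model is
$I = A_I\cos(4\pi r/\lambda + \Phi_I) + B_I$,
$Q = A_Q\sin(4\pi r/\lambda + \Phi_Q) + B_Q$. Hardware imbalance turns the
ideal origin-centered circle into an offset rotated ellipse.
`fit_ellipse()` uses the constrained direct least-squares conic fit in its
numerically stable form — deterministic, needs only five distinct points —
and recovers the channel parameters from the ellipse shape matrix
($MM^\top$ entries give $A_I^2$, $A_Q^2$ and $-A_IA_Q\sin\Delta\Phi$).
`correct_iq()` re-centers, rotates and rescales; because that map is
orientation-preserving whenever $|\Delta\Phi| < 90^\circ$, the polar angle
of the corrected cloud equals the true modulation phase up to a constant.
`arctangent_demodulate()` then unwraps $\mathrm{atan2}(Q, I)$ (mandatory
once displacement exceeds $\lambda/4$) and scales by $\lambda/4\pi$. The
ellipse is fitted per analysis window by default behavior of
`cw_to_displacement(window_seconds=)`, or globally (the default), the two
differing little on stable hardware. 2 kHz recordings are decimated to a
configurable 50 Hz (two-stage zero-phase Butterworth anti-aliasing) before
fitting: the Hankel SVD at 2 kHz would be needlessly expensive and every
retained harmonic lives below 20 Hz.

**UWB (impulse)**: the radargram (fast time × slow time) is cleaned by
per-range-bin mean subtraction (static clutter removal), optionally aligned
by circular cross-correlation of each column with the first column
(integer-bin motion compensation; ties go to the smallest-magnitude lag,
negative first; sub-bin alignment is out of scope), and the row with
maximal slow-time standard deviation is the target bin. The order —
clutter removal, motion compensation, bin selection, extraction — follows
the moving-subject processing chain.

# The synthetic generator

`gen_displacement()` emulates what the pipeline assumes about real data:
a breathing cosine series (defaults: 2 mm fundamental at 0.3 Hz with
0.8/0.5/0.4 mm harmonics — the 4th harmonic deliberately outweighs the
heartbeat, preserving the band-pass failure regime), plus a heartbeat
harmonic series (0.3 mm fundamental at 1.1 Hz) locked to a *jittered beat
schedule*: the beat phase is piecewise-linear through beat times generated
by integrating the rate track with 2% multiplicative interval noise, so
beat-to-beat variability has an exact ground truth. White noise is added at
a stated SNR relative to the clean signal. The default resting rate sits
away from low-order breathing multiples; a heartbeat parked on a breathing
harmonic is a degenerate configuration in which frequency-based separation
is impossible by construction (the adversarial benchmark probes the nearby
1.6 Hz-vs-1.8 Hz case explicitly). `gen_cw_iq()` and `gen_radargram()`
forward-model the two sensors, the latter with an analytic
Gaussian-modulated echo (delay shift $2r/c$ evaluated exactly, so sub-bin
motion is faithful), static clutter, optional integer-bin bulk motion, and
seeded noise.

What the generator does *not* emulate: multipath and multi-target returns,
pulse-shape variability of real artery pulsation (real pulses are not
harmonic stacks peaking exactly at the beat), sensor drift, and motion
artifacts beyond rigid integer-bin shifts. Passing tests therefore
demonstrate correctness of the algorithms under the stated model, not
clinical performance.

# Beat detection and scoring

`detect_beats()` finds local maxima with topographic prominence of at least
0.3 × signal RMS and a minimum separation of 60/max_rate seconds, refined
to sub-sample precision by parabolic interpolation. `vital_beats()` centers
the admissible window on the pipeline's own rate estimate and trims one
beat period from each end, where reconstruction transients live.
`plausible_rates()` applies standard HRV artifact rejection (intervals
implying a rate outside ±30% of the estimate are missed/spurious peaks,
not variability). `compare_rates()` pairs estimated and reference
beat-to-beat values by nearest timestamp within half the median reference
interval and reports RMSE, bias, 95% limits of agreement and Pearson r —
the pairing rule is ours, so absolute agreement numbers from other
pipelines are not directly comparable.

# Baselines

The VMD baseline is the original alternating-direction scheme (mirror
extension, Wiener-filtered spectral slices, center-frequency centroid
updates) with K = 9 modes, penalty 2000, tolerance $10^{-7}$, uniform
initialization, no DC mode — all deterministic. Mode selection mirrors the
pole rules with mean instantaneous frequency (amplitude-weighted) and mean
energy from the Hilbert analytic signal, including the harmonic-presence
disambiguation between competing heartbeat modes. Mode agreement is
assessed away from the first/last half second: the mirrored boundary has a
known edge taper. The band-pass baseline is a 4th-order Butterworth applied
forward-backward — zero phase, so peak timing is preserved and the
comparison isolates the selection failure, not filter delay.

# Problem sizes and benchmarks

The shipped benchmarks run at desk scale: 16–30 s signals at 50 Hz
(1 500 samples, pencil parameter 500, model orders up to ~80), 200-draw
exact-recovery sweeps, and 20-seed scenario comparisons — each suite
finishes in well under a minute on one core. `adversarial_benchmark()`
(0.6 Hz breathing with a strong 1.8 Hz third harmonic beside a 1.6 Hz
heartbeat at 15 dB SNR) and `cw_decay_benchmark()` (120→110 bpm decay
through the full CW chain) are exported so the reported comparisons are
reproducible one call deep.

# Known limitations

* Model-order selection is the `tol` ratio rule only (no AIC/MDL), and the
  standard pencil (no total-least-squares or forward-backward variants).
* Motion compensation is integer-bin and single-receiver.
* Heartbeat-on-harmonic collisions (rate within the matching tolerance of
  $k f_b$) are unresolvable by frequency membership; the harmonic-presence
  check mitigates but cannot eliminate this.
* Window-level rate tracking limits how fast a changing heart rate can be
  followed (~one estimate per window stride).
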