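# vitalpencil

Non-contact vital-sign monitoring with microwave radar: extracting
respiration and **beat-to-beat heart rate** from continuous-wave (CW)
Doppler and ultra-wideband (UWB) impulse radar signals with the **matrix
pencil method** (MPM).

## The problem

A microwave sensor pointed at (or placed on) a person measures chest-wall
and artery displacement, a superposition of breathing (0.1–0.4 Hz at rest,
millimeters), the heartbeat (0.8–2 Hz, tenths of a millimeter), their
harmonics, and noise. Breathing harmonics routinely reach into the heart
band with *more* energy than the heartbeat itself, so a band-pass filter
locks onto the wrong component, and Fourier methods lack the resolution to
remove a harmonic sitting next to the heart line without removing the
heartbeat too.

## The estimator

The displacement signal is modeled as a sum of damped complex exponentials,

y(kTs) ≈ Σᵢ Rᵢ zᵢᵏ,  zᵢ = exp(sᵢTs),  sᵢ = αᵢ + j2πfᵢ,

fitted by the matrix pencil method: a Hankel matrix of the samples is
SVD-truncated at a noise threshold `tol` (model order M = number of singular
values with σᵢ/σ₁ > tol), the poles zᵢ are the eigenvalues of the pencil
`{Y2 − λY1}` in the M-dimensional filtered subspace, and the residues Rᵢ
solve the Vandermonde least-squares system. Separation is then performed in
the *pole domain*: the strongest pole in the breathing band and every pole
at a multiple of its frequency form the breathing family and are removed;
the strongest remaining pole in the heart band, with its first four
harmonics, reconstructs the artery-pulsation waveform, whose peak-to-peak
intervals give beat-to-beat heart rate. Because the breathing family is
removed by *frequency membership*, a breathing harmonic that outweighs the
heartbeat does no harm — the failure case of band-pass extraction.

The package also implements the two comparison methods (variational mode
decomposition with Hilbert–Huang mode selection, and zero-phase Butterworth
band-pass), CW preprocessing (ellipse-fit I/Q imbalance correction and
arctangent demodulation), UWB radargram preprocessing (static clutter
removal, cross-correlation motion compensation, range-bin selection),
Bland–Altman agreement scoring, and a fully seeded synthetic-data generator
for both sensor types.

## Worked example

```r
library(vitalpencil)

# a 30 s resting scenario: 0.3 Hz breathing (2 mm, 4 harmonics),
# 1.1 Hz heartbeat (0.3 mm, 4 harmonics) with 2% interval jitter, 20 dB SNR
d <- gen_displacement(vital_config(seed = 3))

v <- extract_vitals(d$displacement, tol = 1e-2)
v
#> Vital-sign estimate (matrix pencil pipeline)
#>   breathing rate: 0.300 Hz
#>   heart rate:     1.104 Hz (66.2 bpm)

beats <- vital_beats(v)                    # peaks of the reconstructed pulsation
cmp <- compare_rates(beat_to_beat(beats),
                     beat_to_beat(beat_series(d$beat_times, "truth")))
cmp
#> agreement over 31 pairs:
#>   RMSE  1.12 bpm
#>   bias  +0.16 bpm
#>   LoA   [-2.04, +2.36] bpm
```

The breathing and heart rates are recovered to a few mHz, and the
beat-to-beat heart rate tracked to ~1 beat/min — against ground truth the
generator itself wrote.

A low-level fit is a classed model object with the usual methods:

```r
fit <- mpm(d$displacement, tol = 1e-2)   # class "mpm"
coef(fit)                                # pole table (f, damping, residue)
plot(fit)                                # pole strength vs frequency
predict(fit, indices = find_breathing(fit)$indices)  # respiration waveform
```

A thin CLI over the same functions ships in `inst/cli/vitalpencil.R`.

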