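---
title: "Separating, featurizing and classifying bed-pressure signals"
author: "bcgsleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating, featurizing and classifying bed-pressure signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcgsleep)
```

## The measurement problem

A piezoelectric pressure film under a mattress sees everything the body
does: each heartbeat ejects blood into the aorta and the recoil shakes the
torso (the ballistocardiogram, BCG, with its H–I–J–K–L–M–N wave complex
and energy between roughly 0.5 and 20 Hz), the chest rises and falls with
breathing at 0.2–0.4 Hz, the electronics add a DC baseline, and movement
plus sensor physics add broadband noise. The recorded channel is the sum
of all of these. Apnea screening needs the two physiological components
apart again: respiration to segment breaths and judge their shape, BCG to
count and time heartbeats within each breath.

## Wavelet band separation

A dyadic discrete wavelet transform splits the band 0–25 Hz (at 50 Hz
sampling) in halves, five times. The package implements the DB5
(Daubechies, 5 vanishing moments) analysis/synthesis bank directly:
half-point symmetric boundary extension, per-level coefficient lengths
$\lfloor (n_j + 9)/2 \rfloor$, and an inverse that reproduces the input to
relative $10^{-8}$ or better for arbitrary signals — the test suite
asserts both perfect reconstruction and the additivity of single-band
reconstructions. DB5 is a good match here: its scaling function resembles
a breath wave, and five levels put the whole respiration band into the
approximation:

| band | Hz (fs = 50) | content |
|------|--------------|---------|
| D1 | 12.5–25 | mostly noise, a little BCG |
| D2 | 6.25–12.5 | BCG core |
| D3 | 3.125–6.25 | low-frequency BCG, some motion |
| D4 | 1.5625–3.125 | motion |
| D5 | 0.7813–1.5625 | motion + breath harmonics |
| A5 | 0–0.7813 | respiration + DC baseline |

`separate()` reconstructs respiration from A5 alone (mean-subtracted to
drop the baseline) and BCG from D1–D3, after soft-thresholding D1 — the
noise-dominated level — at the universal threshold
$\lambda = \hat\sigma\sqrt{2\ln N}$ with the MAD noise estimate
$\hat\sigma = \mathrm{median}(|D1|)/0.6745$. The threshold selection rule
is a package choice (the separation idea itself does not pin one down);
the universal rule is standard, scales linearly with signal amplitude, and
vanishes for noise-free inputs. Thresholding of D2–D3 is available via
`threshold_levels` but off by default, since those bands carry most of the
BCG energy.

Two deliberate trade-offs:

* **D5 and the respiration channel.** An asymmetric breath wave (inhale
  faster than exhale) has harmonics at 3× the breath rate, 0.9–1.2 Hz —
  inside D5. The default A5-only reconstruction discards them, which
  smooths the wave and can shift the flat end-inspiration trough by up to
  ~0.3 s, because the decimated transform is not shift-invariant in its
  transition band. `include_d5_resp = TRUE` keeps D5 and localizes trough
  boundaries to within ±3 samples on clean synthetic data, at the price of
  admitting more motion energy. Breath *durations* and the ξ statistic are
  nearly unaffected either way, so the default follows the band map's
  designation of D5 as mostly body movement.
* **Non-50 Hz inputs** are accepted; the level count grows until the
  approximation band top edge is at or below 0.8 Hz, and the BCG
  reconstruction takes every detail band lying wholly above ~3 Hz.

## J-peak detection

The separated BCG is normalized to unit maximum per processing window, so
the amplitude threshold (USH, default 0.02) is a fraction of the largest
peak and detection is invariant to channel gain. Candidate local maxima
above threshold are accepted greedily in descending amplitude order, each
accepted peak opening a 220 ms refractory window (no physiological heart
beats faster than ~300/min; at 50 Hz this equals the 0.22 s minimum
peak-to-peak spacing, DSH — both are enforced). Correction then uses the
mean inter-peak interval of the window: pairs closer than 0.4·mean lose
the smaller peak (iterated to a fixed point, earlier peak kept on ties);
gaps wider than 1.66·mean are re-searched once with the threshold relaxed
by 0.5; gaps still empty are recorded as arrhythmia rather than invented.

The base threshold of 0.02 admits essentially everything above the noise
floor — including the low-amplitude skirts that band-limited
reconstruction necessarily leaves around each wave complex (2–9 % of the J
amplitude, just outside the refractory window). The working threshold
therefore adds an adaptive offset, on by default:
$\mathrm{bias} = 0.3\,(q_{90} - \mathrm{USH})$, where $q_{90}$ is the 90th
percentile of the refractory-accepted candidate heights. Anchoring to an
upper quantile of the height distribution tracks the J-peak mode and is
robust to how many sub-threshold wiggles exist; with it, clean synthetic
recordings are detected with sensitivity and positive predictive value of
exactly 1. A fixed offset remains available (`adaptive_bias = FALSE`).

Under noise at 10 dB SNR the L lobe (the next positive deflection, ~0.1 s
after J) occasionally overtakes J and detection lands on it. For
beat-level accuracy statements the package's tests therefore match
detected to true beats within half the refractory window (±110 ms) — the
widest window that cannot double-match — while waveform-level claims on
clean data use ±2 samples.

## Breath frames and features

Frames are trough-to-trough slices: the end of exhalation is the peak of
the pressure wave, the end of inspiration its trough. Troughs are local
minima with prominence at least 25 % of the robust (5th–95th percentile)
channel amplitude and at least 1 s apart; admissible breath periods are
1–15 s (4–60 breaths/min). Frames longer than 15 s — sustained apnea —
are split into equal sub-frames of at most 15 s and flagged; a channel
with no detectable troughs at all falls back to flagged fixed 5 s frames.

Per frame, with $B_n$ the J-peak sample indices and $F_n$ the sampling
rate: AVNN is the mean of $(B_{n+1}-B_n)/F_n$ in seconds, SDNN their
sample standard deviation (one interval gives 0), CV = SDNN/AVNN, the
breath period $T_i = C_i/F_n$ from the frame's sample count $C_i$, and the
beat count. Frames with fewer than two beats leave the interval features
undefined (`NA`); they keep $T_i$ and ξ, are excluded from classifier
training, and are median-imputed (training medians) at prediction time.
Two readings in the source material differ on CV's orientation; the
package follows "variability over mean" and exposes `cv_reciprocal` for
the inverted form.

## The similarity statistic ξ

Respiration amplitude varies across people and sensor placements, so
breath shape is compared, not size. The frame and a standard one-cycle
breath template (built-in raised cosine, 40 % inhale fraction;
user-suppliable) are both normalized to zero mean and unit energy after
resampling the template to the frame length; then

$$\xi = \frac{\max_n R_{f,g}(n)}{\max_n R_{f,f}(n)} \times 100\,\%,
\qquad R_{f,g}(n) = \sum_k f_k\, g_{k+n},$$

the cross-correlation running over every lag with any overlap
(zero-padded outside). Unit energy makes $\max R_{f,f} = 1$ and bounds ξ
at 100 by Cauchy–Schwarz; the normalization realizes the goal of making
the comparison intensity-free ("entropy normalization" in the source
tradition). `cross_correlation()` accumulates sums directly rather than
via FFT, so integer inputs give exact integer results — the tests hold it
to exact equality against an independent double-loop oracle.

Behaviour worth knowing: ξ(f, f) = 100 exactly and ξ is invariant to
positive scaling and offsets of the frame. It is *not* exactly invariant
to segmentation phase: a frame cut late is a circular shift of the cycle,
and a linearly-lagged correlation cannot realign the wrapped part. Shifts
up to ~2 % of the frame length move ξ by under 2 points; even a 10 % shift
leaves a normal breath far above the decision region (measured ≈ 85).
Near-flat apnea frames — 5 % residual breathing plus in-band noise — score
well under 40 because what remains after per-frame normalization is
band-limited noise whose best lag alignment with a single-hump template is
weak.

## Classification

A binomial logistic regression on the six features, fitted by maximizing
$l(w) = \sum_i [y_i\, w\cdot x_i - \ln(1+e^{w\cdot x_i})]$ over the
intercept-augmented weight vector. Newton's method is the default (the
Hessian solve carries a $10^{-8}$ ridge jitter; step halving guarantees a
non-decreasing likelihood trace); gradient ascent with backtracking is the
alternative and reaches the same maximum to $10^{-6}$. Features are
centered and scaled internally for conditioning — interval features are
seconds while ξ is percent — and weights are reported on both scales;
predictions are scale-exact. Synthetic apnea frames are near-separable on
ξ alone, so the fitter detects (near-)separation, warns, and returns the
ridge-stabilized finite solution. Ties at the decision threshold
(default v = 0.5) classify as apnea, following the ≥ convention.

Training mirrors a subject-wise protocol: synthetic "subjects" are
distinct seed/configuration pairs, and no frame from a test subject enters
training.

## The synthetic generator

`synthesize()` emits DC offset + respiration + BCG train + optional motion
transients + Gaussian noise, with exact ground truth (J-peak samples,
trough samples, frame labels, clean component channels). Defaults are the
nominal study conditions: 50 Hz sampling, 0.3 Hz raised-cosine breathing
(40 % inhale fraction) of unit amplitude, 70 bpm with 20 ms beat-to-beat
jitter, BCG amplitude half the breathing excursion, noise off unless
`noise_sd` or `snr_db` (RMS-based) is given. The BCG beat is a sum of
seven signed Gaussian lobes reproducing the H–N extremum sequence with J
dominant; the wave complex occupies a fixed ~0.35 s regardless of heart
rate, as in recorded beats. Two details matter for spectral fidelity:
beats are laid down in continuous time (fractional-sample offsets) and the
negative lobes are scaled so each pulse integrates to exactly zero —
otherwise grid quantization and pulse area leak energy below the heart
rate into the respiration band, which the physiological BCG does not do.

Apnea events hold the respiration at its end-inspiration (post-inhalation
type) or end-expiration (post-exhalation) level with the oscillation
attenuated to 5 % — not zero, so segmentation still sees a continuous
channel — while the heart keeps beating. Motion artifacts are
exponentially decaying random transients, off by default; their shape is a
stand-in, since real film-sensor artifacts are not characterized enough to
model faithfully.

What the generator does *not* emulate: body-position changes that alter
coupling gain mid-recording, heart-rate drift, obstructive-apnea breathing
effort against a closed airway (it models central-type silence), snoring
oscillations, and non-Gaussian sensor noise. Passing tests therefore show
the pipeline correct under its stated signal model, not performance on
clinical recordings.

## Numerical choices and degenerate inputs

* Sample indices are 0-based everywhere in files and frame bounds; all
  intervals are half-open.
* Equal-amplitude close peaks: the earlier is kept (determinism).
* `fit_mle` requires both classes and at least m+1 samples; undefined
  features abort training rather than being silently imputed.
* Zero-energy frames give ξ = 0; an all-flat BCG channel gives an empty
  peak list, not an error.
* Bland–Altman counts boundary points as within the limits (closed
  interval) and fixes the difference direction as estimate − reference.
* Test problem sizes: 40–300 s records, 20-seed Monte-Carlo sweeps,
  n = 2000 for parameter recovery — small enough for a laptop minute,
  large enough for the asymptotics they probe.

## Known limitations

The band plan assumes the heart rate stays above ~3 Hz in its harmonics
and the breath rate below 0.8 Hz; extreme bradypnea/tachypnea would need a
different level count. mean(JJ) correction assumes a roughly stationary
rhythm within a window; long arrhythmic runs are flagged, not corrected.
The logistic model is linear in the six features by design — the aim is a
transparent, engineering-friendly classifier, not maximal accuracy.
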