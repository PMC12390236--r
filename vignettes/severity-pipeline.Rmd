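---
title: "From wrist-worn inertial signals to Parkinson's symptom severities: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From wrist-worn inertial signals to Parkinson's symptom severities: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clinical management of Parkinson's disease depends on repeated assessment
of four cardinal motor symptoms — tremor, bradykinesia, muscle stiffness
and dyskinesia — and of the patient's overall treatment-response state.
Clinician ratings are ordinal (0 = absent to 4 = very severe per symptom;
−4 = severe parkinsonian symptoms through 0 = optimal to +4 = severe
dyskinesia for the overall state) and are only available at check-ups.
`pdsense` implements a pipeline that regresses these ratings on features
extracted from 30 s tri-axial accelerometer and gyroscope recordings
(50 Hz) collected during three standardized exercises: rest (hands on
knees), postural (arms extended) and pronation–supination, performed with
a smartphone held in the examined hand and an armband on the forearm.

Because clinical recordings of this kind are not publicly deposited, the
package ships a synthetic cohort generator that reproduces the statistical
structure the analysis depends on, so every stage — filtering, the feature
bank, selection, model training, grouped validation, class-balanced
evaluation — is exercised end-to-end by code anyone can run.

## The synthetic cohort

Each patient carries latent trait severities drawn from per-symptom class
weights that are deliberately imbalanced towards low severities, with
severity-4 dyskinesia nearly absent (weight 0.02) — the regime in which
class-balanced metrics matter. Examination labels jitter around the trait
by ±1 with probability 0.15 each. The number of examinations per patient
is `1 + Poisson(2.07)` (mean ≈ 3.07), ages are drawn near 62 ± 11 years
and disease duration near 10.5 ± 6 years.

Each recording is built additively, per channel, at 1500 samples:

* **Tremor**: a sinusoid at a frequency drawn uniformly from 4–6 Hz (the
  physiological tremor band), amplitude `0.18 · label^1.3`, expressed most
  strongly at rest (gain 1.0), attenuated posturally (0.7) and
  amplitude-modulated by the voluntary movement during
  pronation–supination (0.5).
* **Bradykinesia**: the voluntary pronation–supination oscillation slows
  and shrinks with the label — rate `2.0 · (1 − 0.18 · label)` Hz,
  amplitude `1.6 · (1 − 0.15 · label)`.
* **Dyskinesia**: a smooth irregular process band-limited to 1–3 Hz with
  base amplitude `0.20 · label`, multiplied by a mean-one lognormal factor
  (log-sd 0.6) drawn per recording. The fluctuation emulates the
  medication-cycle dependence of dyskinetic expression and makes
  dyskinesia the least cleanly encoded symptom — matching its role as the
  hardest target in practice.
* **Stiffness**: all motion components are multiplied by
  `1 − 0.16 · label`, shrinking motion variance with rigidity.
* Accelerometer channels carry a gravity DC offset (9.81 on the nominal
  vertical axis); every recording receives a random device-axis rotation of
  at most 15°, because the sensors are not worn in a fixed orientation;
  white measurement noise (sd 0.05) is added per axis.

The overall treatment-response state is derived as the dyskinesia score
minus the equal-weight mean of the three parkinsonian scores, plus
independent clinician and patient observer noise (sd 0.5), clipped to
[−4, 4] and reported on a 0.5 grid. The algebra is an assumption — ratings
scales are not defined by a formula — but it preserves the scale's
semantics: the two poles are reached exactly when either symptom family is
maximal and the other absent.

**What passing tests do and do not show.** The generator encodes each
symptom in the signal property the analysis is designed to detect, so
end-to-end recovery demonstrates that the pipeline's plumbing — filters,
feature definitions, fold hygiene, metric algebra — is correct, and that
the feature bank carries enough information to separate
severity-monotone encodings. It does not demonstrate clinical validity:
real tremor is non-sinusoidal and intermittent, bradykinesia shows
sequence effects and hesitations, stiffness barely moves the raw signal
at all, and label noise in clinic is not independent Gaussian. Numeric
scores on the synthetic cohort must not be read as expected clinical
performance.

## Signal conditioning

All filters are 4th-order Butterworth applied forward–backward
(zero-phase), with odd-reflection padding at both ends so that boundary
transients decay in the padding rather than in the data:

* 0.1 Hz high-pass on accelerometer axes removes the gravitational DC
  component (gyroscopes have none, and keeping their slow content is the
  physically coherent choice).
* 20 Hz low-pass on everything: motor symptoms live well below 20 Hz at a
  50 Hz sampling rate.
* The magnitude channel `M = sqrt(X² + Y² + Z²)` is computed from the
  filtered axes; it is invariant under device-axis rotation, which is why
  it is carried as a fourth channel everywhere.

Spectra are estimated by Welch's method: 4 s Hann segments, 50 % overlap,
per-segment mean removal, one-sided density scaling (integrated PSD ≈
variance). The band decomposition into 0–3, 3–9 and 9–14 Hz exists both as
filters (`band_decompose`, a 3 Hz low-pass and two band-passes) and —
for the feature bank — as masks over PSD bins. The mask route computes one
spectrum per channel instead of four filtered signals per channel, and a
tone inside one band lands in exactly one mask, which also makes the band
features exactly additive over the spectrum. The "full" band is 0–25 Hz
(Nyquist).

## The feature bank

Per recording, features are computed on four channels (X, Y, Z, M):

| block | per channel | total |
|---|---|---|
| time domain (mean, sd, median, skewness, excess kurtosis, max, min, IQR, approximate entropy, sample entropy, power, absolute mean difference) | 12 | 48 |
| frequency domain × 4 bands (max power, its frequency, mean spectral power, weighted mean power, spectral kurtosis/skewness/IQR, centroid) | 32 | 128 |
| STFT (4 s window, 2 s hop → 14 windows; mean/sd/skewness/min/max of per-window mean PSD) × 4 bands | 20 | 80 |
| windowed range and histogram entropy (non-overlapping 4 s windows, 5 statistics each) | 10 | 40 |
| 3-level Daubechies-10 DWT detail means and sds | 6 | 24 |
| axis-pair Pearson correlations | — | 3 |

Total: 323 sensor features per recording, plus one-hot metadata (affected
side, handedness, group) and age / years-since-diagnosis at examination.

Numerical choices worth stating:

* Skewness uses the adjusted Fisher–Pearson form
  `n/((n−1)(n−2)) Σ((x−x̄)/s)³`; kurtosis is the excess form
  `n Σ(x−x̄)⁴ / (Σ(x−x̄)²)² − 3`. Both (and correlations, centroid,
  weighted mean power) are defined as 0 on zero-variance or zero-power
  input so feature tables are always finite.
* The *absolute mean difference* splits the signal at `⌊n/2⌋` and takes
  the absolute difference of the half means.
* *Weighted mean power* is normalized by the sum of frequencies, `Σ p·f /
  Σ f` — a nonstandard but deliberate definition (it scales the spectral
  first moment by a constant grid factor rather than by total power, so it
  grows with absolute band power, unlike the centroid).
* Approximate and sample entropy use embedding `m = 2` and tolerance
  `r = 0.2 · sd`, the conventional defaults, with Chebyshev distance; both
  are implemented in C++ in one shared O(n²) template sweep because a
  cohort run makes thousands of per-channel calls.
* The windowed "entropy" is the Shannon entropy of a 16-bin amplitude
  histogram per window — one operational definition among several in use;
  it is monotone in amplitude spread structure, not in amplitude itself.
* The DWT uses hard-coded Daubechies-10 analysis filters with symmetric
  padding; at 50 Hz the detail levels cover roughly 12.5–25, 6.25–12.5 and
  3.125–6.25 Hz. For white noise the detail sds are equal across levels
  (the transform is orthonormal), so tests check tone concentration at the
  right level, not a level ordering.
* A 12-per-channel time-domain block gives 48 features per recording; a
  printed per-recording figure of 44 circulates for banks of this shape
  and is inconsistent with 12 × 4 — the per-block arithmetic here is
  treated as normative, and `time_entropy = "magnitude_only"` exposes a
  reduced variant (317) that drops the two entropies on the raw axes.

## Feature selection

Step one removes redundancy: iterate column pairs in canonical order and
drop the later member of any pair with `|r| > 0.97` (absolute correlation;
anti-correlated duplicates are equally redundant). Step two ranks the
survivors by random-forest impurity importance, keeps the top 60 %
(ceiling), then walks the ranking greedily: a candidate is retained only
if the 5-fold cross-validated R² strictly improves. "Strictly" is the
simplest faithful reading of *improvement*; an `epsilon` argument exposes
a tolerance because tree-model CV scores fluctuate, and on a pure-noise
target chance fluctuations would otherwise admit features.

Selection is leak-free by construction when run inside each training fold
(`cross_validate(selection = ...)`); the cohort-scale experiments in this
package instead run pruning and ranking once globally and skip the greedy
stage, trading a small optimistic bias for a large constant-factor
speed-up — with ~1300 features and 200 models per grid this is the
difference between minutes and hours. The greedy stage is exercised and
asserted on constructed data where its behavior is provable.

## Models, validation, metrics

Three regressor families with their implementation defaults: random
forest (`ranger`), gradient-boosted trees (`xgboost`, 100 rounds,
`reg:squarederror`) and an RBF support-vector regressor (`e1071`).
Features are z-scored with statistics fitted on the training fold only.
Validation is shuffled 10-fold or leave-one-patient-out, where each fold's
test set is all examinations of one patient — the scheme that measures
generalization to unseen patients and is immune to repeated-examination
leakage.

Metrics: MSE, R², MAE and Pearson's r on the raw predictions, plus
class-balanced variants for the imbalanced ordinal targets: true values
are discretized to their label grid (integers for symptoms, 0.5 for the
state), MAE and MSE are computed per class, and `bMAE`/`bMSE` average
over the classes present. With equal class counts they reduce exactly to
MAE/MSE. Zero-variance truth makes R² and r undefined; they are reported
as `NA` with a `degenerate` flag, never silently as 0. Predictions are
clipped to the valid range as post-processing (`clip_predictions`);
metrics are computed on unclipped values by default, with clipping never
increasing MAE or MSE when the truth lies inside the range.

Permutation importance is the mean decrease in R² over 10 shuffles per
feature. It is best evaluated on held-out rows; on training rows tree
ensembles assign small spurious importance to memorized noise.

## Problem sizes

The cohort-scale experiments (tests and the acceptance script) use 200
patients (~600 examinations) with four accelerometer blocks per
examination — both devices, rest and pronation–supination exercises, one
hand — about 2400 recordings and 1302 feature columns. These sizes were
chosen as the smallest at which grouped-CV estimates are stable enough to
compare scopes and schemes; the analysis scripts under `analysis/` use a
40-patient cohort for a faster narrative run. The full 24-block grid is
the generator default and is exercised structurally in the tests.

## Known limitations

* The generator's severity encodings are smooth and monotone by
  construction; it does not model medication cycles over time, diurnal
  fluctuation, intermittent tremor, or sensor dropout within a recording.
* The treatment-response composition rule and the 0.5 label grid are
  assumptions (scales are defined clinically, not algebraically).
* Gyroscope channels skip the 0.1 Hz high-pass; if real gyroscopes carry
  slow drift, an explicit detrend would be needed.
* `bMSE` averages per-class MSEs, so a single badly-predicted rare class
  dominates it — that is the point of the metric, but it makes it noisy
  when a class has very few members.
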