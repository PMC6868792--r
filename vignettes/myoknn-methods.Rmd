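---
title: "Models and methods behind myoknn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind myoknn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoknn)
```

`myoknn` implements a complete myoelectric decoding and evaluation stack —
feature extraction, training-label construction, a K-nearest-neighbor (KNN)
velocity decoder, a closed-loop posture-matching task, and the associated
signal-quality and statistical analyses — driven entirely by a synthetic
EMG generator. This vignette documents the models, the tunable parameters
and their defaults, the numerical choices, and what the synthetic setting
does and does not establish about real recordings.

## The signal model

The generator treats each of `n_muscles` (default 8) muscles as a
directionally tuned source in the three-DOF intent space
(pronation/supination, wrist flexion/extension, hand open/close). Muscle
$m$ has a unit-norm tuning vector $w_m$; its activation under an intent
$u(t) \in [-1,1]^3$ is rectified-linear,

$$a_m(t) = b + \max(0,\; w_m \cdot u(t)),$$

with baseline $b$ (default 0: resting muscle is modeled as electrically
silent). Rectification reflects that a muscle pulls in one direction only;
opposing motion is produced by antagonist muscles, which is why the default
tuning set is three jittered agonist/antagonist pairs along the DOF axes
plus two oblique muscles. The EMG carrier is wide-sense-stationary
band-limited Gaussian noise — white noise passed (zero-phase, both
directions) through the recording chain's 4th-order Butterworth 15–375 Hz
bandpass at 2 kHz and scaled to unit RMS — amplitude-modulated by $a_m(t)$
interpolated to the sample rate. Real EMG is an interference pattern of
motor-unit action potentials; a Gaussian carrier reproduces its second-order
(amplitude and spectral) statistics, which is all that MAV/WFL features
see, and is chosen for analyzability. Motor-unit structure, fatigue, and
force generation are out of scope.

Channels are a non-negative mixture of the muscle sources through a
crosstalk matrix with unit row sums, plus white sensor noise. Two presets
model the electrode conditions:

* **intramuscular** — near-selective channels (99% own muscle, 0.5% to
  each circular neighbor; off-diagonal mass ≤ 2%) and a 34 dB SNR preset;
* **surface** — a circumferential ring whose channels each blend five
  neighboring muscles (weights 0.4/0.2/0.2/0.1/0.1) and a 25 dB preset.

The presets mirror the reported separation between implanted and surface
recordings; both are plain defaults, fully configurable. SNR is defined
operationally as the ratio, in dB, of channel RMS over intent-active
samples to channel RMS over zero-intent samples; the sensor-noise variance
is solved per channel so the realized ratio equals the target
(`realized_snr()` is the generator's own oracle, and with $b = 0$ the
calibration is exact up to sampling error, well within ±1.5 dB).
24-bit quantization is not modeled — it is negligible at these SNRs.

The virtual subject closing the loop is proportional-with-saturation:
intent is the ROM-normalized target error times a gain (default 2),
clipped to $[-1,1]$, with Gaussian intent noise (SD 0.05) and a 200 ms
reaction delay. No user model is claimed beyond this; the defaults are a
deliberately plain stand-in for a cooperative participant.

## Features and labels

Features are computed on 200 ms windows every 50 ms: per channel the mean
absolute value (MAV) and waveform length (WFL), MAV block first, channel
order preserved — 16 dimensions for 8 channels. Windows are 0-based and
half-open, and a frame is stamped with its window's **end** time: a feature
at $t$ summarizes the preceding 200 ms, matching causal online use (the
alignment convention is isolated in `sliding_windows()`). Trailing partial
windows are dropped, never zero-padded. Each dimension is divided by its
training maximum; online features may exceed 1 and are not clipped —
Euclidean distance tolerates mild extrapolation, and clipping would
discard effort information.

The training protocol presents all $3^3 = 27$ posture codes
$\{-1,0,+1\}^3$ in seeded random order, `repetitions` times (default 5),
with Prepare/Go/Rest phases of 2/2/1 s. The active-movement window of a
trial runs from Go onset to 1.5 s past Go offset, reflecting that muscle
activity regularly outlasts the cue. Labels ("assumed intent") are zero
outside every active window; inside, the trial's code is scaled by
momentary effort

$$e(t) = \frac{\bar{m}(t)}{\langle \bar{m} \rangle_{\text{window}}},$$

where $\bar m(t)$ is the mean MAV across channels. Two readings of the
effort normalization were possible — a time-varying profile or a single
per-trial scalar; the time-varying form is the default because it produces
labels that ramp with the actual contraction, and the scalar form is
retained behind `per_trial_scalar = TRUE` for sensitivity analysis.
Effort is clipped to $[0,1]$ so labels stay inside the code cube
(`clip_effort = FALSE` disables this for inspection). Where an active
window would overlap a later trial's phases, frames go to the **earlier**
trial: activity there is the tail of the movement already underway, not a
response to a cue the subject has not yet acted on. The synthetic training
intent itself ramps up in 100 ms and down in 300 ms at a plateau effort of
0.8 — a "low to moderate" sustained contraction; the ramp shape is a free
modeling choice.

## The decoder

`knn_decoder()` stores the normalized training features and their targets
verbatim (a lazy learner — nothing is estimated at fit time). Prediction
finds the $K = 100$ training frames nearest in Euclidean distance and
returns the inverse-distance-weighted mean of their targets,
$w_k = 1/(d_k + \varepsilon)$, clipped to $[-1,1]$ (a no-op in exact
arithmetic, kept as a contract). Numerical choices:

* $\varepsilon = 10^{-9}$ regularizes exact matches so the online and
  leave-one-out paths share one code path, rather than special-casing
  $d = 0$;
* ties at the $K$-th distance break by ascending training-row index —
  reproducibility over micro-optimization; predictions are otherwise
  invariant to training-row permutation;
* neighbor selection uses a partial sort with a stable trim, verified in
  tests against a brute-force full-sort oracle to $10^{-10}$.

`loo_vaf()` reports per-DOF variance accounted for,
$\mathrm{VAF}_d = 100\,(1 - \mathrm{var}(t_d - \hat v_d)/\mathrm{var}(t_d))$,
excluding only the identical frame by default (leave-one-sample-out);
`by_trial = TRUE` excludes the query's whole trial, which is the stricter
variant when temporally adjacent frames are nearly duplicates.

## The task engine

The closed loop runs at 50 ms: subject intent (reaction-delayed) →
one 200 ms constant-intent EMG window → features, normalized with the
**training** scale → KNN → threshold/gain shaping → integration, saturated
at the ROM bounds. Generating each online window independently at constant
intent is an approximation to a continuously evolving signal; it preserves
the feature statistics the decoder sees, which is what matters at the
50 ms control cadence. The sensor-noise SD is frozen at its training
calibration (`calibrate_generator()`), because training and online
features must share one amplitude scale — exactly as a real system's
normalization is fixed at training time.

Controller defaults: dead-zone threshold 0.10 of the normalized command
range per DOF, gain 3 (user-preference values in the study setting;
allowed up to 10), `max_speed` of one full ROM per second per DOF
(180°/s, 130°/s, 100%/s) mapping a saturated command to physical velocity.
Success requires all three DOFs simultaneously within ±15% of ROM
(closed: exactly 15% counts) for 20 **consecutive** frames — leaving
tolerance resets the dwell counter, the strictest reading of a 1 s hold —
within a 30 s timeout. The hand state carries over between trials inside a
block (consecutive-target separation is then meaningful) and resets to
neutral at block boundaries.

Metrics: success rate; trial time (dwell-inclusive, 30 s flagged for
failures); path efficiency = 100 × straight-line / traveled distance, in
ROM-normalized coordinates so degrees and percent are commensurable, and
measured to the point where the successful dwell **began** — holding still
on target should not count as travel (`end_index` exposes the choice, and
failed trials contribute PE over their full 30 s and are included in
summaries by default). Arm-posture conditions are represented as
label-only metadata on sessions: the generator's intramuscular signals are
posture-invariant by construction, which is the modeled claim about
implanted electrodes.

## Signal quality

Crosstalk is the matrix of zero-lag Pearson correlations of the raw
band-limited signals — the quantity a unit-diagonal correlation heat map
implies; envelopes are deliberately not used, since envelope correlation
conflates co-activation with electrical crosstalk. Both signed and
absolute off-diagonal means are available (`absolute = TRUE`), as a signed
mean can hide magnitude.

The burst-SNR estimator is this package's own operationalization (the
algorithm it stands in for is external to the repo): envelope = 2 Hz
zero-phase low-passed rectified signal; noise RMS from the lower Otsu
class of the **log**-envelope histogram (log domain keeps the split robust
when activity dominates the recording); burst detection at envelope
> 3 × noise RMS; a final mask re-thresholded at the midpoint of the quiet
and burst envelope levels, whose crossings sit at the true burst edges
regardless of amplitude, giving an unbiased duty cycle; and active/quiet
RMS computed outside a 0.25 s guard band around mask transitions, since
envelope smoothing blurs edges and a handful of mislabeled high-amplitude
samples would otherwise dominate the quiet RMS. Against generator ground
truth the estimator is accurate to ±0.2 dB and ±0.02 duty over
SNR ∈ {15…35} dB and duty ∈ {1/3, 1/2, 2/3}; the tests assert the looser
±2 dB / ±0.05.

Box's M (chi-square approximation by default, F approximation behind
`method = "F"`) compares channel covariance structure between conditions;
at one variable it reduces to variance-ratio behavior, which the tests
cross-check against an F-test oracle.

## Stability statistics

The controller-stability regression has **no common week main effect**:
the design is intercept, controller indicator (0 = intact-hand reference,
1 = KNN), and controller-specific week slopes — the interaction-only
structure that a nested ANOVA (`compare_models_anova()`, selection at
p < 0.05) retains when either controller's performance trends over time.
Trial times use an optional reciprocal transform to remedy non-normal
errors; on the $1/y$ scale a slower controller has a negative coefficient.
Observations are treated as independent trials (hundreds of trials per
controller, consistent with the modest $R^2$ such designs produce);
session-level clustering is a known limitation, not modeled — a
mixed-effects extension is deliberately out of scope.
`simulate_stability_table()` generates data from this exact model for
parameter-recovery and power studies; its default coefficients
(66.9, −21.8, 3.4, 0.6) echo the magnitudes such studies report.

## Problem sizes, determinism and limitations

All randomness flows through explicit integer seeds, each generator
restores the caller's RNG state, and every pipeline stage is
bitwise-reproducible given its configuration (`run_pipeline()` writes a
manifest with seeds and content hashes). The test suite and the acceptance
script use the protocol at its native scale for training (27 × 5 cued
trials, 675 s of 8-channel EMG at 2 kHz ≈ 13 500 feature frames) and
scaled-down evaluation (16-target sessions across 5 task seeds; SNR
recovery on 8-cycle contraction trains; 200–500-replicate null
simulations for the tests' size checks) — sizes chosen to exercise every
code path at full fidelity while keeping a complete run in minutes on one
core.

What passing tests show — and what they do not: the synthetic subject
yields near-ceiling decoding (leave-one-out VAF ≈ 99%, 100% closed-loop
success) because its muscle tunings are stationary, its carriers are
Gaussian, and its intent policy is cooperative. Real intramuscular
recordings add electrode micro-motion, co-contraction, day-to-day intent
drift and fatigue, none of which are modeled; the package's claims are
therefore about the **correctness of the pipeline** (features, labels,
decoder, task logic, metrics, estimators and tests, each against
independent oracles or ground truth), and about qualitative contrasts the
generator encodes — intramuscular beats surface on crosstalk and SNR for
matched sources — not about reproducing participant-specific performance
numbers.
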