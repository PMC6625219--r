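---
title: "Decoding evoked clinical pain from fNIRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding evoked clinical pain from fNIRS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Functional near-infrared spectroscopy (fNIRS) measures cortical
hemodynamics optically: near-infrared light (~700-1000 nm) crosses the
scalp and skull, and the attenuation changes at two wavelengths resolve
concentration changes of oxygenated (HbO) and deoxygenated (HbR)
hemoglobin. Because the instrument is portable and chair-compatible, it
is a practical candidate for *objective pain assessment*: decoding, in
real time, whether a patient is in pain and on which side of the body.

`nirspain` implements a complete decoding framework for an evoked
dental-pain protocol: a 40-channel probe over bilateral prefrontal
cortex (PFC) and bilateral primary somatosensory cortex (S1), sampled at
20 Hz during descending cold stimulation of a hypersensitive tooth.
Two cortical signatures carry the information: an expectation-evoked
response in *bilateral* PFC that begins before the moment pain is
reported, and a two-peak response in the S1 *contralateral* to the
stimulated side (the orofacial somatotopic representation is
lateralized; laterality is what makes left/right localization
possible).

Real recordings of this protocol are not publicly deposited, so the
package is organized around a synthetic generator that reproduces the
protocol's structure and label bookkeeping exactly, and every
downstream stage is validated against it. Published accuracies from the
clinical feasibility study (80.37% pain/no-pain, 74.23% three-class)
were obtained on patient data and are **not** reproducible from
synthetic recordings; what is reproducible -- and what the test suite
checks -- are the protocol's counting identities, the metric identities
implied by the published tables, and the qualitative properties of the
method (class-weighting direction, decoding above chance, causality).

## The synthetic protocol generator

`simulate_subject()` emulates one session:

| parameter | default | meaning |
|---|---|---|
| `n_trials` | 20 | descending cold stimulations per session |
| `start_temp` | 32 °C | thermode baseline |
| `ramp_rate` | -2 °C/s | cooling rate until the subject clicks |
| `threshold_mean`, `threshold_sd` | 5, 3 °C | cohort distribution of pain thresholds |
| `baseline_s` | 12 s | pre-ramp hold (absorbs the inter-trial interval) |
| `post_click_s` | 12 s | recording retained after the click |
| `pain_label_s` | 5 s | post-click window labeled "pain" |

The pain-label window is the one bookkeeping constant the protocol
fixes: 5 s at 20 Hz is 100 samples per trial, so a 20-trial session
contributes exactly 2000 pain-labeled samples, matching the published
per-subject counts. The threshold distribution (mean 5 °C) reflects
hypersensitive subjects who tolerate most of the 32 → 0 °C ramp; with
the default epoch lengths it yields a cohort pain fraction of ~13%,
close to the published 13.24%. A `click_miss_prob` option reproduces
sessions in which a trial ends without a click (such trials contribute
no pain labels).

Hemodynamics are injected as HbO time courses built from a canonical
double-gamma hemodynamic response function (peak 6 s, undershoot 16 s,
undershoot ratio 1/6 -- the standard shape; the study reports no
functional form): a bilateral PFC response starting 4 s before each
click (the expectation phase) and two S1 kernels 4 s apart at the click
(the two-peak pain response), confined to the hemisphere contralateral
to the stimulated side. HbR is anticorrelated at a fixed -1/3 ratio.
The forward optics are the exact modified Beer-Lambert model used in
preprocessing (shared constants), so the inverse chain can be tested to
machine precision. Physiological noise -- cardiac (1.1 Hz), respiratory
(0.25 Hz) and Mayer (0.1 Hz) oscillations with channel-random phase,
white noise, and linear drift -- is added in optical-density units.

What the generator does **not** emulate: motion artifacts, scalp/skin
blood flow (short-separation regression is out of scope), anatomical
variability in channel sensitivity, habituation across trials, and the
much lower effective signal-to-noise of real clinical recordings.
Passing tests on synthetic data therefore demonstrate correctness of
the machinery, not clinical-grade performance.

## Preprocessing

The chain is quality control → optical density → band-pass → modified
Beer-Lambert inversion (`preprocess_pipeline()`):

* **Optical density.** $OD(t) = -\ln(I(t)/I_0)$ per channel and
  wavelength; $I_0$ is the mean intensity over the first 10 s.
* **Band-pass.** 0.01-0.3 Hz, 3rd-order Butterworth applied
  forward-backward (zero phase, so the effective response is the squared
  magnitude). Zero-phase filtering preserves the relative timing of the
  PFC/S1 cascade that the features depend on. The design gives ≥ 60 dB
  attenuation at the 1 Hz cardiac line and < 0.01 dB loss at 0.05 Hz.
  Edge transients of the very low high-pass edge are tamed by
  odd-symmetric reflection padding (1.5 periods of the low cutoff).
* **MBLL.** Per channel, the 2×2 system
  $\Delta OD(\lambda) = \ln(10)\, d\, DPF(\lambda)\,
  [\varepsilon_{HbO}(\lambda)\Delta HbO +
  \varepsilon_{HbR}(\lambda)\Delta HbR]$
  is solved for $(\Delta HbO, \Delta HbR)$ (µM). Defaults: 690/830 nm,
  bundled Gratzer/Prahl extinction coefficients, DPF 6.0, separation
  3 cm -- all overridable; the study reports none of these constants.
  Filtering is applied to OD *before* the inversion; both operations are
  linear, so the order is a determinism convention, pinned by a test.
* **Quality control** (two steps, thresholds configurable): step 1
  flags channels whose mean intensity leaves the dynamic range or whose
  coefficient of variation is outside $[10^{-6}, 0.15]$ (a clipped,
  dead channel has CV ≈ 0); step 2 requires a cardiac spectral peak at
  ≥ 5× the median 0.5-2 Hz periodogram power -- a channel in optical
  contact with the scalp shows the pulse. Failing channels are masked,
  never dropped from the channel axis.

## Feature cubes

Classifier inputs are history cubes of shape T × 40 × 2 (time ×
channels × [HbO, HbR]):

* **Type I** (`make_type1_cubes()`): T = 40, the 2-s block ending at
  the anchor sample; the label is the state at the anchor.
* **Type II** (`make_type2_cubes()`): T = 80, the 2-s block ending at
  the anchor concatenated with a second 2-s block `lag` samples
  earlier (default 8 s, total 10 s of history). The split design exists
  because the expectation-phase PFC response precedes the pain phase;
  block A sees it while block B sees the S1 response. At deployment the
  pain moment is unknowable, so both blocks are anchored to the current
  frame with a fixed lag; anchoring block A at the per-trial threshold
  instead is a training-time alternative, not the default.

Cubes are strictly causal (no window reaches past its anchor -- a
property test perturbs future samples and asserts invariance) and are
materialized lazily, so million-cube sets carry no memory cost until a
training batch is drawn.

**Streaming normalization.** To merge subjects for the localization
task, signals are normalized in real time by a causal divide-by-the-mean:
each sample is divided by the windowed mean (default 30 s; the window
length is a package choice) of samples up to and including itself.
`stream_normalize()` implements this on any series with an
$\varepsilon$-sign guard ($\varepsilon = 10^{-9}$) and a clamp
(default ±10): on *zero-mean* signals such as band-passed concentration
changes the running mean crosses zero and the raw quotient degenerates,
so unclamped outputs can reach $10^9$. The package therefore also
provides `normalize_recording()`, which applies the same causal scheme
to the raw light intensities -- the natural target, since intensity has
a stable positive baseline (the running mean ≈ $I_0$), the quotient
stays near 1, and between-subject gain and coupling differences cancel
exactly where they arise. The bundled localization experiment
normalizes intensities; the hemoglobin-series path remains available
and contract-tested.

**Class balancing.** `class_weights()` provides the fixed 10:1
pain:no-pain loss weighting used for the detection task and an
inverse-frequency scheme (weights ∝ 1/count, minimum 1);
`oversample()` balances classes by seeded duplication and is applied
inside training folds only -- `cross_validate()` enforces this so test
folds are never resampled.

## The classifier families

Six small families are compared: a 3-layer dense network (ANN),
convolutional networks with 5, 6 and 7 weighted layers (CNN-5/6/7), a
simple recurrent network, and an LSTM. The comparison that motivated
this package states only the *depths*; all widths, kernels and training
settings here are this package's reconstruction:

* ANN: flatten → dense 128 → dense 64 → output.
* CNN-5: conv 16(3×3) → conv 32(3×3) → maxpool 2×2 → dense 64 →
  dense 32 → output; CNN-6 inserts conv 64(3×3) after the pool; CNN-7
  additionally widens the head with dense 128.
* RNN/LSTM: one recurrent layer (hidden 64) over the time axis, each
  step seeing the 80 channel×chromophore values, then a dense output.

Layers with trainable weights (dense, conv, recurrent) count toward
the family depth; pooling and flatten do not. A structural test audits
3/5/6/7. Training is mini-batch Adam (lr $10^{-3}$, batch 64, default
20 epochs, no early stopping), with class-weighted softmax
cross-entropy (weights normalized per batch) and a global gradient-norm
clip (5) for stability on heavy-tailed normalized features. Everything
is seed-deterministic: initialization, shuffling and oversampling all
derive from explicit seeds, and no function touches the global RNG
state. The engine is written in R with explicit forward/backward
passes; gradients of every layer type are verified against central
finite differences to ~$10^{-7}$.

Because the published layer internals, optimizer and epoch counts are
unknown, printed accuracies cannot be matched even in distribution;
they are treated as context, not targets.

## Evaluation

`metrics()` reports the clinical panel: accuracy, sensitivity
TP/(TP+FN), specificity TN/(TN+FP), positive likelihood ratio
sens/(1−spec), PPV, NPV, and Cohen's kappa from the confusion-matrix
marginals. Conventions:

* **3-class tasks**: accuracy and kappa are computed on the full 3×3
  table; sensitivity/specificity/PPV/NPV/PLR answer the clinical
  pain-vs-no-pain question, so codes {1, 2} are pooled as positive.
  A macro one-vs-rest average is available via `multiclass = "macro"`.
* Zero denominators are flagged (`$flags`), and PLR at specificity 1 is
  reported as `Inf` with a flag -- never a silent number.
* `reconstruct_from_summary()` rebuilds real-valued confusion counts
  from published (sensitivity, specificity, prevalence, n); feeding the
  result back to `metrics()` recovers every derivable cell of a
  published table row. `check_operating_points()` does this for the
  bundled reference tables and flags rows whose printed PLR disagrees
  with recomputation by one printing unit.

`cross_validate()` defaults to **trial-blocked** folds: overlapping
2-s windows make sample-shuffled splits optimistic because nearly
identical cubes from the same trial land on both sides of the split.
Sample-shuffled and subject-blocked modes are available, and reports
always name the mode. The no-cross-validation single split used for
merged-subject localization is `holdout_evaluate()` (trial-blocked
holdout). Chance reference for end-to-end checks is the
majority-class predictor with binomial sampling noise
(`null_accuracy()`); the cube count is used as n, which overstates the
effective sample size of overlapping windows -- a conservative caveat
noted here rather than corrected, since the observed margins are tens
of standard deviations.

## Real-time engine

`run_stream()` replays a hemoglobin series frame by frame: causal cube
assembly, optional causal normalization, inference, one frame per
sample (decimation optional). Causality is structural -- truncating the
input after time t cannot change any frame at ≤ t (tested at bit
level) -- and streaming output is identical to batch prediction over
the same cubes because both share one code path. Frames serialize to
newline-delimited JSON (`{t, hbo[40], hbr[40], state, prob[K], model}`,
6 significant digits); state codes are 0 = no pain, 1 = right-side
pain, 2 = left-side pain. The downstream augmented-reality renderer is
out of scope; `stream_sink()` is a reference consumer that validates
the schema and tallies states.

## Bundled experiments and problem sizes

The `experiment_*()` functions are the package's reference analyses;
the test suite and `scripts/acceptance.R` call exactly these, at sizes
chosen to run on a laptop CPU in a few minutes:

* `experiment_cohort_bookkeeping()`: 12 subjects, default protocol --
  verifies 2000 pain cubes per subject and the cohort pain fraction.
* `experiment_forward_inverse()`: noise-free subject -- MBLL round trip
  at machine precision, < 1% recovery error against band-passed truth,
  > 0.95 correlation with the raw injected time courses.
* `experiment_detection()`: 4 subjects × 8 trials, type-I cubes at
  stride 3, ANN, 5-fold trial-blocked CV, 6 epochs.
* `experiment_localization()`: left-pain + right-pain subjects,
  intensity-stream normalization, merged 3-class set, ANN on a
  trial-blocked holdout, 8 epochs.
* `experiment_weighting()`: one subject with a 10:1 no-pain:pain
  protocol, ANN trained 2 epochs with vs without 10:1 loss weights from
  identical initializations, 10 paired seeds. This experiment scales
  the response amplitudes by 0.15: at the generator's default
  amplitudes the synthetic task saturates sensitivity at 1.0 for both
  arms, and the weighting *direction* -- the property under test -- is
  only observable at a mid-range operating point, which is also where
  the published sensitivities (0.14-0.41) sit. Generator defaults are
  unchanged.

## Numerical notes and limitations

* Filter edge handling: odd-symmetric reflection padding, capped at the
  series length; series shorter than ~3 filter lengths are rejected.
* Normalization guards: $\varepsilon = 10^{-9}$ with the sign of the
  mean; clamp ±10 (dimensionless after division).
* Argmax ties in prediction resolve to the first (lowest) class code.
* Determinism is bitwise under a fixed BLAS thread policy; training
  logs are compared at $10^{-12}$ tolerance to allow for reduction-order
  differences.
* SNIRF (HDF5) I/O is not included in this build; recordings exchange
  via a lossless JSON container (doubles serialized at 17 significant
  digits) or a long-format CSV for toy fixtures.
* The generator's laterality is idealized (exactly zero ipsilateral S1
  response); real recordings show partial ipsilateral activity, so
  synthetic localization accuracy overstates what channel geometry
  alone can deliver on patients.
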