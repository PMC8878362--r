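---
title: "Surface EMG pattern recognition: methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface EMG pattern recognition: methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the methods implemented in `emgpr`, the parameters
they expose, and the reasoning behind the non-obvious choices. The package
models the standard embedded myoelectric-control design: two surface EMG
channels over the wrist flexor and extensor muscle groups drive a four-class
motion decoder (`GRASP`, `FLEXION`, `EXTENSION`, `RELAX`) which in turn
drives a simulated prosthetic hand.

```{r setup}
library(emgpr)
```

## 1. Synthetic signal model

No human recordings ship with the package; `generate_session()` produces
labelled sessions from a generative model whose defaults mirror a typical
acquisition protocol:

* **Sampling rate** `fs = 1000` Hz — standard for surface EMG, whose usable
  power lies below ~450 Hz.
* **Protocol** (`session_protocol()`): 10 repetitions of each of the four
  motions, 2 s holds, and 2–3 s relaxed transitions between holds. One
  session is roughly three minutes of signal.
* **Carrier**: Gaussian white noise bandpass-filtered to 25–445 Hz
  (order 4) and normalised to unit RMS. Surface EMG is well approximated by
  amplitude-modulated band-limited noise; the carrier band sits strictly
  inside the analysis band so filtering does not distort class structure.
* **Envelope**: per-motion, per-channel activation gains — e.g. `GRASP`
  activates both channels (4.0 flexor, 2.5 extensor), `FLEXION` is
  flexor-dominant (5.0 / 1.2), `EXTENSION` extensor-dominant (1.2 / 5.0),
  `RELAX` is baseline only. A resting baseline of 0.05 RMS units models
  sensor and tissue noise. 200 ms activation ramps are placed *inside* the
  transition segments, so hold windows are stationary and transitions carry
  the `TRANSITION` label (excluded from training by default, as in cued
  protocols where inter-cue data is discarded).
* **Interference**: an additive 50 Hz sinusoid (amplitude 0.005, i.e. 10 %
  of baseline) models power-line pickup, giving the notch filter something
  real to remove.
* **Inter-subject variability**: `sample_subject(seed, variability)` scales
  each subject's baseline log-normally, `exp(v z)`, and moves activation
  gains by `1 + (g - 1) exp(v z)` with `v = 0.3` by default. This produces
  cohorts where subjects are mutually recognisable but not identical — the
  property needed to study pooled versus subject-wise evaluation.

`generate_cohort(n, ..., seed)` derives one independent sub-seed per subject
with `derive_seed()`, so any cohort is reproducible from a single integer.

What this generator does and does not show: it reproduces the *amplitude
structure* that time-domain EMG features measure, so relative comparisons
(feature sets, classifiers, split schemes) behave like they do on real data.
It does not model electrode shift, fatigue, crosstalk dynamics, or realistic
spectral changes with force, so absolute accuracies are optimistic and no
clinical conclusion should be drawn from them.

## 2. Preprocessing

`default_filters(fs)` applies, in order:

1. **50 Hz notch** (`design_notch`): a constrained-pole-zero biquad with a
   transfer-function zero exactly on 50 Hz and quality factor `Q = 30`
   (≈1.7 Hz stop bandwidth), the standard minimal-distortion line filter.
2. **Bandpass 20–500 Hz, order 6** (`design_bandpass`): Butterworth, built
   from an order-3 low/high prototype (`signal::butter`), so "order 6"
   refers to the final bandpass polynomial degree. The 20 Hz edge removes
   motion artefact and baseline drift; the upper edge keeps the EMG band.
   At `fs = 1000` Hz a 500 Hz upper cutoff sits exactly on Nyquist, which a
   digital bandpass cannot realise; rather than erroring on the conventional
   parameterisation, the edge is clamped to `0.99 * fs / 2 = 495` Hz and the
   clamp recorded in the spec's `$warnings`.

Both filters run through one causal direct-form-II-transposed core
(implemented in C++ for per-sample speed) that carries per-channel state
across blocks. A signal filtered in arbitrary block partitions is therefore
*bit-identical* to one batch call — the property that makes the streaming
pipeline equal to offline processing. Stability is checked at design time by
verifying all poles lie inside the unit circle.

## 3. Windowing and features

`segment_record()` cuts disjoint 100 ms windows (100 samples at 1000 Hz); a
window keeps a motion label only if *all* its samples share that label,
otherwise it is a transition window. 100 ms is the usual embedded
compromise: long enough for stable amplitude estimates, short enough to stay
within real-time control latency budgets.

Per window and channel, four time-domain features (Hudgins-style amplitude
estimators):

* `MAV = mean(|x|)`
* `RMS = sqrt(mean(x^2))`
* `SSI = sum(x^2)`
* `VAR = SSI / (N - 1)` — **without mean subtraction**. Surface EMG is
  treated as zero-mean, so the second moment about zero is used directly;
  this is the common EMG convention rather than the sample variance about
  the mean. `var_td(x, textbook = TRUE)` gives the mean-subtracted version
  for comparison. Two identities follow and are tested exactly:
  `SSI = N * RMS^2` and `VAR = SSI / (N - 1)`, plus `MAV <= RMS`
  (Cauchy–Schwarz).

With four base features there are `2^4 - 1 = 15` non-empty combinations
(`enumerate_combinations()`), and `sweep_grid()` evaluates all of them
against every classifier and split scheme.

## 4. Classifiers

All four classifiers are implemented from scratch behind one
`fit`/`predict` contract, with every tie broken deterministically by the
canonical class order `GRASP < FLEXION < EXTENSION < RELAX` (then
alphabetical for other labels). `e1071` and `rpart` appear only in the test
suite as independent oracles.

* **k-NN** (`knn_fit`): `k = 5`, Minkowski distance with exponent `c = 2`
  (Euclidean). Vote ties break by the smallest summed distance among tied
  classes, then canonical order. Distances are computed in vectorised
  query-chunks so memory stays bounded.
* **Gaussian naive Bayes** (`gnb_fit`): class priors from training
  frequencies, per-class per-feature Gaussians with MLE (1/n) variances,
  plus additive smoothing `1e-9 * max(pooled feature variance)` for
  numerical stability. Posteriors are computed in log space.
* **Entropy decision tree** (`dt_fit`): greedy binary partitioning
  maximising information gain in bits, candidate thresholds at midpoints
  between consecutive distinct sorted feature values, `max_depth = 3` (a
  shallow, embedded-friendly tree: at most 8 leaves for 4 classes),
  `min_leaf = 1`. An impure node with a valid cut is split even when the
  immediate gain is zero — a positive-gain stopping rule would make
  XOR-like patterns unlearnable at any depth.
* **RBF SVM** (`svm_fit`): one-vs-one binary machines, RBF kernel with
  `gamma = 1/n_features`, box constraint `C = 1`. Each sub-problem is
  solved by sequential minimal optimisation with maximal-violating-pair
  working-set selection and the analytic two-variable update; the offset is
  recovered from free support vectors (KKT-interior points). Multiclass
  prediction is by vote, ties broken by the largest aggregate signed
  decision value, then canonical order. The dual constraints
  (`0 <= alpha <= C`, `sum(alpha * y) = 0`) are exposed on the fitted model
  and asserted in tests.

A practical note on the SVM: with raw amplitude features (whose scales span
orders of magnitude between `MAV` and `SSI`) and `gamma = 1/n_features`, the
RBF machine underfits badly relative to the other three classifiers. That is
a genuine property of unscaled EMG features, not a solver defect — the SMO
matches `e1071::svm` on matched problems. `evaluate_model(...,
standardize = TRUE)` z-scores features with training-set statistics if you
want to see the scaled behaviour.

## 5. Evaluation schemes

`split_dataset()` implements the two schemes whose contrast matters in EMG
work:

* **Pooled** (`"pooled"`): all subjects' windows pooled, an unstratified
  random 80/20 split. Test windows come from subjects seen in training, so
  this measures within-subject decodability.
* **Subject-wise** (`"subject_wise"`): whole subjects held out (default:
  the last two of the cohort). This measures generalisation to unseen
  users, the deployment-relevant number.

On 10-subject default cohorts the MAV + depth-3 tree reaches roughly 94 %
pooled and 75 % subject-wise — the characteristic ~20-point generalisation
gap. `compare_schemes(acc1, acc2)` runs Welch's t-test over accuracy
samples (with a deterministic degenerate branch when both samples have zero
variance). `evaluate_model()` also reports per-window prediction time; the
timing is informational and never used as a pass/fail criterion.

Typical problem sizes: one default session is ~180,000 samples and 760
labelled windows; a 10-subject cohort gives ~7,600 windows of 8 features.
The full 15-combination × 4-classifier × 2-scheme sweep is the largest
supported experiment.

## 6. Staged runtime

`run_pipeline()` mirrors a multi-threaded embedded controller with four
stages — acquisition, feature extraction, classification, motor command —
connected by *latest-value mailboxes* (`mailbox()`): single-slot channels
where writers overwrite and readers always see the freshest value, with a
version counter and a pre-defined initial value (`RELAX`, code 3, so the
hand rests before the first classification).

In `"replay"` mode the stages are scheduled in lock step, so the emitted
code sequence is exactly `classify_record()`'s offline output regardless of
the source block size — verified bit-for-bit in tests. In `"realtime"` mode
each stage consumes the freshest value and overwritten versions are counted
as drops. `motion_to_actuation()` maps codes to the simulated hand: `GRASP`
drives all five finger strokes to 20 mm, `RELAX` to 0 mm, `FLEXION` /
`EXTENSION` set the wrist to −45° / +45°; strokes clamp to [0, 20] mm, the
wrist to ±60°, and every mapping is idempotent. `measure_latency()`
evaluates the event log against a latency budget (default 100 ms, one
window).

## 7. Limitations

* The generator's stationary, amplitude-only class structure makes pooled
  problems easier than real EMG; absolute accuracies should be read as
  upper bounds and only *relative* comparisons taken seriously.
* `VAR` without mean subtraction inflates the feature when a window has a
  nonzero mean (e.g. residual drift below the bandpass edge).
* The SVM is scale-sensitive (see above) and, being an O(n²) dual solver in
  R, is practical up to a few thousand training windows, not the full
  cohort sweep.
* The runtime is a faithful *simulation* of a staged controller —
  scheduling is cooperative, not preemptive, so it demonstrates dataflow
  correctness and determinism, not true concurrency.
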