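---
title: "Decoding motor tasks from EEG with self-organizing polynomial networks"
author: "gmdheeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor tasks from EEG with self-organizing polynomial networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gmdheeg)
```

## The problem and the model

`gmdheeg` decodes which of eight executed motor tasks (baseline with eyes
open, closing of either hand, dorsal and plantar flexion of either foot,
and inter-task rest) produced a short multichannel EEG epoch. The target
recording geometry is 16 dry electrodes in the 10–10 placement sampled at
125 Hz, with signals band-limited to 7–31 Hz — the passband that retains the
movement-modulated mu (~7.5–12.5 Hz) and beta (~16–31 Hz) sensorimotor
rhythms. The design goal is a classifier whose *entire* inference cost is
known in closed form and small enough for embedded BCI hardware, which rules
out deep convolutional models and motivates the two-stage structure:
hand-crafted spectral/statistical features followed by a compact
self-organizing polynomial network.

### Features

Ten features per electrode, in a fixed order:

* **Band powers** over delta (0.5–4), theta (4–8), alpha (8–13), beta
  (13–30) and gamma (30–50 Hz): `P_b = Σ_{f_low ≤ f_k ≤ f_high} |X(f_k)|²`,
  where `X` is the unnormalized DFT of the full epoch (rectangular window,
  no detrending or zero padding) on the one-sided bins `f_k = k·fs/N`.
  The sum is a plain sum of squared magnitudes — no `1/N` scaling, no Welch
  averaging — so the value depends on epoch length; that is intentional,
  because the classifier standardizes features before fitting.
* **Dominant frequency**: the bin of maximal power among *positive*
  frequencies. The DC bin is excluded (a nonzero mean would otherwise always
  win and the feature is meant to capture rhythmic activity), and ties break
  toward the lower frequency so the value is deterministic.
* **Amplitude statistics**: mean and population standard deviation
  (divide by `N`) of the rectified signal `|x[n]|`, the median of the raw
  signed samples, and the peak-to-peak range `max − min`. The asymmetry —
  two rectified statistics, two signed ones — follows the defining formulas
  as stated; it is documented rather than "fixed".

With 16 channels and the 5 default bands this yields the canonical
160-element descriptor. Both the band list and the channel count are
configurable: `mu_beta_bands()` selects the two-band sensorimotor variant,
and small channel counts keep test fixtures cheap. Two caveats are inherited
from the feature definitions themselves: on 7–31 Hz band-limited data the
delta and most of the gamma band are structurally near zero (the features
are still computed, and the network simply learns to ignore them), and a bin
lying exactly on a shared band boundary (e.g. 4 Hz) is counted in both
adjacent bands because the band limits are inclusive at both ends.

### The GMDH network

Every unit is a two-input quadratic (Ivakhnenko) polynomial

```
y = b0 + b1·x1 + b2·x2 + b3·x1² + b4·x2² + b5·x1·x2
```

with six coefficients fitted by ordinary least squares on the design
`[1, x1, x2, x1², x2², x1·x2]` (minimum-norm SVD solution on rank-deficient
designs, so fitting never fails). Training is the classical inductive GMDH
procedure:

1. z-score the features using location/scale from the training rows only;
2. split the training rows by a seeded shuffle into a fit part and an
   internal validation part (default fraction 0.25) — the *external
   criterion* set;
3. grow hidden layers one at a time: every unordered pair of the previous
   layer's outputs (layer 1: the standardized features) proposes one
   candidate neuron fitted on the fit rows; candidates are ranked by MSE on
   the validation rows and the best `width` survive, ties broken by the
   lexicographic order of the input-index pair;
4. after the last layer, the neuron with the lowest criterion is *selected*
   as the single output — it is not refitted and no combining neuron is
   added, which is what keeps the parameter accounting exact.

The default layer widths are the decremental schedule
40–38–27–22–16–10–8–5: wide early layers explore many pairwise feature
interactions, and the shrinking widths distill them while bounding model
size. Summing the widths gives 166 neurons, hence 6 × 166 = 996 trainable
coefficients, and — at 8 multiplications and 5 additions per neuron —
1,328 + 830 = 2,158 arithmetic operations per forward pass. The profiler
(`count_neurons()`, `count_parameters()`, `count_operations()`,
`profile_model()`) computes these counts from realized layer widths;
feature standardization and the decoding step are deliberately excluded, as
the accounting covers the polynomial network proper.

### Multiclass output encoding

A single output neuron cannot represent eight classes without an encoding.
The default is **ordinal regression on the numeric class code 1–8** with
round-half-up-and-clamp decoding: it is the only reading consistent with
both a single output neuron and the 996-parameter count, and the synthetic
classes (below) are constructed so that code order tracks a monotone
spectral axis. Users who reject the induced ordering can select
`encoding_mode = "one_vs_rest"`, which trains one network per class on 0/1
targets and decodes by argmax at K times the cost. Non-finite raw outputs —
possible when a heavily overfit deep network overflows double precision —
decode to the nearest clamp boundary (`NaN` to class 1), so prediction is
total and ablation accuracies stay well defined.

### Design choices that were genuinely open

* **Layer inputs**: layer `l` consumes only layer `l − 1` outputs, with no
  passthrough of raw features. This matches the decremental-architecture
  reading and keeps the operation count exact; the alternative (re-offering
  raw inputs at every layer) would change both.
* **External criterion**: plain validation MSE — the classical GMDH
  regularity criterion — with an unstratified seeded shuffle. Fraction,
  stratification and criterion are all configurable through `fit_config()`.
* **Candidate explosion**: layer 1 over 160 features fits C(160,2) = 12,720
  candidate neurons. Each is a cheap 6-coefficient solve, and the full sweep
  runs in a few seconds; `max_candidate_pairs` optionally replaces the full
  enumeration with a seeded random subsample of pairs. The shipped
  evaluation runs use a cap of 1,500, which loses little accuracy on the
  synthetic testbed because informative pairs are plentiful.
* **Degenerate layers**: when fewer candidates exist than the schedule
  width, all are kept (realized width < nominal) and the event is logged;
  structural validation checks every stored index against the realized
  widths.

## Evaluation protocol

The package reproduces a two-stage protocol: a stratified 70/30 train/test
split (the unstratified strict reading is a flag), and an independent
stratified 5-fold cross-validation in which every sample is tested exactly
once and feature standardization is refit inside each fold to avoid leakage.
Metrics come from the confusion matrix with rows = true class: accuracy,
Cohen's kappa `(p_o − p_e)/(1 − p_e)`, and per-class precision/recall/F1
with macro and support-weighted aggregates. Division-by-zero conventions set
a metric to 0 (not NaN) so aggregates stay defined on degenerate
predictions; support-weighted recall then equals accuracy identically, which
the tests assert. The test suite also cross-checks all metrics against an
independent reference implementation (`caret`) to 1e−12, with the caveat
that `caret` orients its tables rows = prediction, so the comparison
transposes.

Two ablations mirror the architecture- and feature-design questions:

* **Depth ablation** fits networks of 1–12 hidden layers on one fixed
  split. Depths ≤ 8 truncate the default schedule; beyond 8 the paper-style
  schedule is exhausted, and the extension repeats the final width (5) —
  a choice the schedule itself does not determine, stated here and
  configurable.
* **Feature-subset ablation** masks columns to the frequency group (band
  powers + dominant frequency, 6 per electrode) or the time group (the four
  amplitude statistics), refits, and compares held-out accuracy.

## The synthetic testbed

The generator produces one trial per (subject, class): 60 subjects × 8
tasks = 480 balanced trials by default, 16 channels, 125 Hz, 4 s epochs.
Each class is a *spectral signature*: a dominant sinusoid at a
class-specific frequency (the 8 defaults are evenly spaced over 8–30 Hz,
inside the passband and pairwise distinct) plus secondary mu (10 Hz) and
beta (20 Hz) components whose gains form a distinct per-class grid, all with
random phases per channel, scaled by a per-subject amplitude effect
(`1 + e_s`, `e_s ~ N(0, 0.1²)`), plus white Gaussian noise, then band-limited
to 7–31 Hz by an exact frequency-domain mask (zeroing out-of-band bins —
simple, exact, and free of filter-design ringing). Secondary gains are
capped at 0.5 so the dominant component keeps the largest spectral peak even
under worst-case rectangular-window leakage (~0.41 power ratio at half-bin
offset versus ≤ 0.25 for a bin-centered secondary), which is what makes the
extracted dominant frequency a faithful readout of the signature.

The epoch length is a generator choice, not a recording constant: 4 s at
125 Hz gives 500 samples and 0.25 Hz spectral resolution, comfortably
separating the ~3 Hz class spacing. The loader accepts any length ≥ 2.

**Noise calibration.** `noise_sd` — the one load-bearing free parameter —
was calibrated once and then frozen at 2.5 (2.5× the unit dominant
amplitude). At that level the full pipeline lands near but below its
accuracy ceiling (held-out accuracy roughly 0.92–0.97 across seeds, 5-fold
CV means ~0.94–0.98), a regime where the depth and feature ablations show
real variation instead of saturating at 100%. At this noise level the
frequency-domain features remain strongly informative while the time-domain
statistics are dominated by noise, so the feature ablation ranks
frequency ≫ time, and networks deepened past 8 layers degrade — the same
qualitative orderings the architecture was designed around.

**What passing tests do and do not show.** The generator encodes class
structure *spectrally* because the classifier's features are spectral; it
contains no 1/f background, no event-related
desynchronization/synchronization dynamics, no volume conduction or
electrode-geometry effects, and no artifacts. Accuracy numbers on this
testbed therefore validate the pipeline's mechanics (feature correctness,
selection, decoding, evaluation) and its qualitative orderings — they are
not estimates of performance on real recordings. The subject effect is an
amplitude scalar only, which makes explicit the subject-dependent protocol
assumption that train and test share subject-specific signal
characteristics; a leave-one-subject-out protocol is out of scope.

## Numerical choices and degenerate inputs

* Least squares via pivoted QR (`.lm.fit`); rank < 6 triggers an SVD
  pseudoinverse (relative threshold 1e−12) giving the minimum-norm solution.
* Dominant frequency of an all-zero or constant channel is undefined and
  raises an error naming the channel; band power of an empty band is 0.
* `round`-half-up (`floor(y + 0.5)`) is used for decoding rather than R's
  banker's rounding, so decoding is monotone in the raw output.
* All randomness (generation, splits, folds, pair subsampling) flows from
  explicit seeds; one master seed fans out to stage seeds by fixed offsets.
  Rerunning any pipeline or CLI invocation with the same config reproduces
  every artifact byte-for-byte.
* Kappa is undefined when the expected agreement is 1 (all mass in one
  row-and-column); the report stores `NA` in that case rather than failing.

## Problem sizes used in the shipped checks

The end-to-end checks run at the default study conditions (480 trials,
160 features) with the layer-1 candidate sweep capped at 1,500 seeded pairs;
one such fit takes on the order of a second, and the complete test suite and
the acceptance script each run in well under a minute. Unit tests use much
smaller fixtures (two-class Gaussian blobs, 1–3-channel trials) chosen so
that brute-force oracles — explicit `lm()` fits per candidate pair,
hand-computed DFTs, enumerated selections — stay exact and fast.

## Known limitations

* The ordinal output encoding imposes a class order; with real data, where
  no such order exists, the one-vs-rest mode is the safer (costlier)
  choice.
* Band powers double-count bins on shared band boundaries (inclusive
  limits), and their scale depends on epoch length (unnormalized DFT).
* The generator's realism limits are listed above; in particular, near-zero
  delta/gamma power is structural on band-limited data, synthetic or real.
* No EDF/BDF/BrainVision readers: real recordings enter through the
  per-trial CSV + manifest convention documented in `?read_manifest`.
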