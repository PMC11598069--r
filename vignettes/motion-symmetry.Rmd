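---
title: "Quantifying left/right motion symmetry from paired accelerometer recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying left/right motion symmetry from paired accelerometer recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accsym)
```

## The measurement problem

Rehabilitation exercises — for instance core-strengthening movements
prescribed before abdominal surgery — are ideally performed symmetrically:
the left and right limbs should move with the same vigour and the same
rhythm. A smartphone's built-in 3-axis accelerometer, strapped first to one
limb and then the other (or to two phones simultaneously), records each
side's motion as a time series of accelerations at a nominal 100 Hz. The
question this package answers is: *given one recording per side of the same
exercise, how asymmetric was the movement, and how confidently can a
classifier tell the two sides apart?* Those are two views of the same
quantity — a perfectly symmetric movement yields indistinguishable sides —
and the package computes both.

## From raw traces to features

Each recording is trimmed (default 1 s at each end, where the signal is
contaminated by handling the phone; the amount is a free parameter because
no principled value exists), reduced to a single channel, and cut into `M`
consecutive segments of `N` samples. The default `M = 10` assigns one
segment per repetition in the common ten-repetition protocol; `N` follows
by floor division and trailing samples are discarded. The segments of both
sides form the columns of a signal matrix `D` (`N` rows, `Q = 2M` columns,
left block first), the package's central intermediate object.

The default channel is the Euclidean magnitude
`sqrt(ax^2 + ay^2 + az^2)`. The alternative — picking one axis — is exposed
via the `channel` option, but magnitude is the default because it is
invariant to how the phone was oriented on the limb, the least controllable
aspect of a home-exercise protocol.

Each column is then described by:

* **time-domain features** — its mean and its sample standard deviation
  (`n - 1` denominator throughout the package, matching how printed cohort
  tables report spreads);
* **frequency-domain features** — relative band powers. Each column has its
  mean removed and is transformed by the DFT (`stats::mvfft`); for a band
  `[fc1, fc2)` the relative power is the in-band sum of `|g(k)|^2` divided
  by the total over bins `1..floor(N/2)`. Mean removal zeroes the DC bin,
  so the denominator measures motion energy only. Bands are half-open so
  adjacent bands partition the spectrum; with even `N` the Nyquist bin is
  excluded from both sums, a documented convention worth a fraction of a
  percent at most in realistic signals.

The default bands are `[0.5, 3)` Hz and `[3, 10)` Hz: exercise fundamentals
lie around 0.3–2 Hz, and the second band captures harmonics and jerk. The
band edges are free choices — nothing in the methodology pins them — and
they are deliberately coarse; users with a specific exercise catalogue
should tighten them to bracket the observed fundamentals.

Features and one-hot side labels form the pattern matrix `P` (features ×
segments) and target matrix `T` used by both the symmetry criterion and the
classifiers.

## The symmetry index and global criterion

For a feature `r` and segment pair `q`, with left and right values `F_L`
and `F_R` (both non-negative),

```
c_q(r) = 50 * |F_L - F_R| / (F_L + F_R)
```

ranges from 0 (identical) to 50 (one side motionless). The absolute value
makes the index a magnitude; a signed variant is available behind
`signed = TRUE` for directionality analysis. Two degenerate-input rules are
fixed: `0/0` (no motion on either side) scores 0 and is counted in the
result's `degenerate` field, and negative inputs are an error — which is
why the segment *mean* is excluded from the symmetry presets: magnitude
means sit near the gravity baseline and can, after baseline effects, take
either sign, making the ratio meaningless.

The global criterion `C` averages `c_q(r)` over the `M` pairs within each
feature and then over the chosen feature set. The inner average is
normalized by the number of pairs actually summed (`M`): an index exists
per left/right *pair*, not per column, and normalizing by the column count
`Q = 2M` would silently halve every criterion value. Two presets select the
feature set: `"frequency"` (band powers only) and `"mixed"` (band powers
plus standard deviation). Both are kept because published per-exercise
tables have been described in both terms, and the choice genuinely changes
the number: band powers are scale-invariant, so a purely amplitude-based
asymmetry is invisible to the `"frequency"` preset and visible to
`"mixed"`.

Per-cohort results aggregate into an individuals × exercises table with row
means, column means and column sample standard deviations, all stored at
full precision and rounded to one decimal only at print/CSV time. The
package ships the published 16 × 8 reference table and participant
metadata (`reference_symmetry()`, `reference_participants()`) so this
aggregation arithmetic is verifiable against printed values without any
raw-data download.

## Classification as a symmetry probe

Segments are classified as left or right using, by default, the two
features named in the reference analysis — the band power of the first band
and the standard deviation — under leave-one-out cross-validation (as many
folds as segments). Confusion counts accumulate over folds with the left
class as positive; the package reports sensitivity, specificity, accuracy
and the misclassification rate `CV`. `CV` is defined here as `1 - AC`; a
published cross-validation *error* need not equal that quantity if it is a
loss rather than a rate, and no attempt is made to reconcile the two.

Three classifiers are implemented:

* **SVM** — radial kernel via `e1071::svm`, cost 1, kernel width
  `1 / (R * var)` on standardized features. No hyperparameter search: the
  classifier is a probe, not the product.
* **Gaussian naive Bayes** — per-class, per-feature Gaussian likelihoods
  with *equal* priors, written in-package because the equal-prior contract
  is part of the method definition here (training folds are nearly but not
  exactly balanced, and empirical priors would leak that imbalance).
  Standard deviations are floored at 1e-9 against degenerate folds.
* **Two-layer neural network** — `R -> 10 sigmoid -> 2 softmax`, trained by
  full-batch gradient descent on the mean cross-entropy, learning rate 0.1
  with step halving whenever a step would increase the loss (so the
  recorded loss is non-increasing), stopping at an improvement below 1e-6
  or 2000 epochs. Glorot-style uniform initialization from a caller seed
  makes every report reproducible; per-fold seeds derive from the report
  seed. Gradients are verified against central finite differences in the
  test suite.

Features are z-scored per row using training-fold statistics only; the
held-out column never influences its own scaling.

## The synthetic-data generator

Because raw study recordings are not bundled, validation rests on a
generator whose asymmetry is known by construction. One record is a
periodic limb motion: per axis, a fundamental at `rep_freq` plus a second
harmonic at half amplitude (giving the spectrum non-trivial band structure
without mimicking any one exercise), Hann-windowed per repetition so each
repetition starts and ends at rest, with fixed per-axis amplitude weights
and phase offsets standing in for the projection of one limb motion onto
three axes. White Gaussian sensor noise is added independently per sample,
axis and side; an optional 0.05 Hz baseline drift models slow sensor wander
and is off by default so that the amplitude identity below holds exactly.

Defaults mirror the reference protocol: 100 Hz sampling, 10 repetitions,
fundamental 0.5 Hz (one repetition per 2 s, mid-range of typical exercise
cadence), amplitude 2 m/s², noise 0.2 m/s² (10% of amplitude). The right
side carries the template with amplitude scaled by `1 + asym_amp` and
frequency by `1 + asym_freq`; with zero noise this forces
`RMS(R)/RMS(L) = 1 + asym_amp` exactly and, at zero asymmetry, L and R are
bit-identical. Cohorts draw per-(individual, exercise) seeds from a master
seed, so an entire simulated study reproduces exactly.

What the generator does *not* emulate — and therefore what green tests do
not establish about real data: exercise-specific kinematics, within-record
fatigue and tempo drift, sensor placement variation, orientation changes
mid-record, and heavy-tailed artifact noise. Passing tests demonstrate that
the pipeline's arithmetic is correct and that its statistics respond to
controlled asymmetry in the expected direction; they do not calibrate what
a clinically meaningful criterion value is, which no threshold in this
package claims to do.

## Numerical and design choices

* DFT bin `k` (1-based) maps to frequency `(k - 1) fs / N`; resolution
  `fs / N` Hz.
* A constant segment has zero spectral energy; its band power is defined
  as 0 with a warning rather than NaN.
* Timestamped input with jitter above 1% of the sample period is linearly
  interpolated onto a uniform grid (the DFT assumes uniform sampling);
  below that threshold the grid is only re-regularized. The resampled
  length stays within one sample of the original.
* Segmentation discards trailing samples silently; a left/right length
  mismatch beyond one segment warns and uses the shorter length.
* LOOCV folds whose training set collapses to one class (impossible with
  `M >= 2`, guarded anyway) predict the majority class with a warning.
* All randomness flows from explicit seed arguments; generators save and
  restore the caller's RNG state.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations use the study-shaped
defaults: 20-second records at 100 Hz, `M = 10` segments, 16 × 8 cohorts
for design counting, 20 seeds per Monte-Carlo condition, 200 segments for
chance-level classification checks, and a 6-level asymmetry sweep for the
symmetry-vs-accuracy consistency property. These sizes give stable
Monte-Carlo means (the seed-averaged criterion is monotone in injected
asymmetry with margin) while keeping a full run in minutes on one CPU.

## Known limitations

* The criterion compares *feature* symmetry, not waveform symmetry: two
  sides with equal band power and spread but different phase structure
  score as symmetric.
* Magnitude reduction discards axis-specific asymmetry; per-axis analysis
  requires running the pipeline per axis via the `channel` option.
* Equal-prior Bayes and the fixed SVM/NN hyperparameters are deliberate
  interpretations where the method definition is silent; they are stated
  here rather than tuned.
* With small `M`, LOOCV accuracy on truly symmetric data is pessimistic
  (below 50% on average) — the well-known leave-one-out imbalance effect —
  so chance-level behaviour is checked on held-out splits, not LOOCV.
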