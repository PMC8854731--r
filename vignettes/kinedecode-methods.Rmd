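---
title: "Decoding individual differences from dance movement: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding individual differences from dance movement: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kinedecode)
```

# Overview

`kinedecode` decodes gender, Big-Five personality traits and genre
preferences from optical motion capture of free dance. This vignette is
the package's own account of the science: the models and their
assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the design choices made where
the method left room.

# Preprocessing model

## From markers to joints

Raw input is a set of reflective-marker trajectories (millimetres,
right-handed coordinates, vertical as the third axis). A
`marker_joint_map` reduces markers to a 20-joint skeleton by per-frame
averaging: the pelvis-centre *root* is the midpoint of two back-hip
markers, the head the mean of three head markers, and the remaining
joints pass single markers through. The default map also partitions the
20 joints into 12 *pair groups* (8 left/right pairs plus 4 axial
singletons), used later for the reduced importance profile.

Occlusion gaps are filled by per-axis linear interpolation, but only for
interior runs up to a configurable length (`max_gap`, default 10
frames); longer gaps and gaps touching a recording boundary are errors,
because extrapolating marker positions silently would corrupt the
covariance structure the features measure.

## Local coordinates

Per frame, joints are translated so the root is the origin and rotated
about the vertical axis so the left-hip-to-right-hip vector lies along
the positive mediolateral axis. The axis convention is frozen
throughout: axis 1 mediolateral, axis 2 anteroposterior, axis 3
vertical. Two consequences matter:

* all downstream features are exactly invariant to where in the capture
  volume the dancer stood and which way they faced (a property the test
  suite checks to 1e-10), and
* only *local* movement — movement within the body — remains; global
  displacement across the floor is removed by construction.

The hip realignment is applied **per frame** by default, so a dancer
turning in place contributes no spurious apparent motion. This is a
genuine design choice: realigning only once per trial (`rotation_mode =
"first-frame"`) preserves within-trial turning as movement and is
available as a switch, but per-frame alignment is the reading that makes
the features orientation-invariant throughout a turning dance.

## Velocity estimation

Two estimators mirror the two capture pipelines the package targets:

* `velocity_butterworth()` — central-difference time differentiation
  (one-sided at the ends, scaled by the sampling rate) followed by a
  zero-phase low-pass Butterworth filter, default order 2, cutoff 24 Hz.
  The filter is applied forward and backward (odd-reflection padding,
  steady-state initial conditions) because a single-pass IIR filter
  would time-shift velocity relative to position; the method literature
  rarely states phase handling, and zero-phase is the only choice that
  keeps the two representations aligned. The design (bilinear transform
  of the analogue prototype) and the forward–backward pass were
  validated against an independent reference implementation, frozen
  into the tests.
* `velocity_savgol()` — Savitzky–Golay first-derivative filtering,
  default window 7 samples, polynomial order 2, scaled by the sampling
  rate. Boundary samples evaluate the derivative of the polynomial
  fitted to the first/last full window, so any trajectory that is
  locally a polynomial of degree ≤ 2 is differentiated exactly
  everywhere — the property the tests assert.

The differentiation stencil ahead of the Butterworth filter is central
differences; "time differentiation" alone does not pin down a stencil,
and the central stencil is second-order accurate and symmetric, which
preserves the sign-flip antisymmetry `v(−x) = −v(x)` both estimators are
tested for.

# Correntropy features

For two equal-length series the package computes

$$K(x_i, x_j) = \exp\!\left(\frac{-\lVert x_i - x_j\rVert_2^2}{2\sigma^2 T^2}\right)$$

a Gaussian-kernel similarity bounded in (0, 1], equal to 1 iff the
series coincide, and monotone decreasing in their distance. Dividing by
\(T^2\) normalises for stimulus length so recordings of different
durations are comparable. Over the 60 univariate coordinate series of a
20-joint local-frame recording this yields a symmetric positive
semidefinite 60 × 60 matrix with unit diagonal; its strictly lower
triangle, enumerated row-major (`dim_i > dim_j`), is the length-1770
feature vector.

Parameter notes:

* **σ (default 12.0)** is interpreted on the millimetre scale of the
  input. The kernel value is strongly unit-dependent; if data arrive in
  other units, `correntropy_matrix(..., unit_scale = )` rescales rather
  than silently changing σ's meaning. The same σ is used for velocity
  features — the method specifies only one bandwidth.
* **T** is the frame count of the trimmed stimulus segment.
* **Dimension order** (joint-major, axes mediolateral/anteroposterior/
  vertical; row-major lower-triangle enumeration) is frozen and recorded
  in `feature_pair_index()`, because the weight-to-joint attribution of
  the importance profiles is only reproducible if every element's joint
  pair is fixed.

An open modelling question is whether the kernel should see each
coordinate axis as its own series (as here) or 3-D joint trajectories
with vector norms; the univariate reading follows the description of
covariance "in each direction" and is the only one that yields 60
dimensions and 1770 features.

# Decoding

One sample is one (participant, stimulus) feature vector;
participant-level labels are replicated across a participant's stimuli.
Cross-validation uses 5 folds. Two fold modes exist, and the choice is
consequential:

* **random** (default) — a seeded shuffle balanced to fold sizes
  differing by at most one. This matches the standard "split the data
  randomly" protocol, but when a participant contributes several
  stimuli, their samples can land on both sides of a split. Because
  joint-covariance features are highly individual (movement signatures
  identify dancers), a model can then predict a held-out sample by
  recognising *the dancer* rather than the trait. This leakage inflates
  apparent regression accuracy.
* **grouped-by-participant** — participants, not samples, are
  partitioned, so no dancer spans folds. This measures generalisation to
  unseen dancers. The package's null-calibration and recovery tests use
  this mode for regression precisely because the random mode's leakage
  would otherwise masquerade as trait signal (measured on null cohorts:
  random-split trait R² ≈ 0.11 from leakage alone, grouped-split R² < 0).

Families:

* **Linear SVM** (gender): squared-hinge primal
  \(\tfrac12\lVert w\rVert^2 + C\sum\max(0, 1 - y_i(w x_i + b))^2\),
  optimised by L-BFGS to a projected-gradient tolerance of 1e-5
  (default `C = 1`; the cost parameter is not specified by the method
  and is exposed). With more features than samples the optimisation is
  run in the span of the training rows, which is exact for this
  objective and an order of magnitude faster at F = 1770. No class
  weighting is applied despite imbalanced cohorts; plain accuracy is the
  reported metric.
* **Bayesian linear regression** (traits, preferences; primary):
  Gaussian prior on weights and Gaussian noise, with both precision
  hyperparameters set by MacKay-style evidence maximisation on the SVD
  of the centred design. The posterior yields per-sample predictive
  standard deviations (`predict_linear_model(..., se = TRUE)`), which
  grow away from the training data — the property the tests check on a
  conjugate 1-D toy. A constant response degenerates gracefully to an
  intercept-only model.
* **Principal-component regression** (secondary): OLS on the leading
  components capturing ≥ 95% of variance (the component rule is this
  package's choice; `variance_kept = 1` reproduces OLS exactly, which is
  tested). The composed length-F weight vector reproduces the
  component-space fit to 1e-10.

R² and RMSE are computed within each fold and averaged; no feature
standardisation is applied by default since correntropy features already
live in (0, 1].

# Joint Importance

For each fold model, the absolute weight of every feature element is
credited to the joint(s) its two dimensions belong to, summed over the 5
fold models, and min-max normalised to [0, 1] per profile. Design
decisions, each made once and documented:

* an element whose two dimensions belong to the **same joint**
  contributes its |w| **once** to that joint — one element, one unit of
  evidence per joint it touches;
* fold weights are **summed**, not averaged — after min-max
  normalisation the two are identical, so the simpler reading is used;
* **pair averaging operates on raw sums**, and the reduced 12-vector is
  then min-max normalised. Averaging already-normalised values would let
  the normalisation anchors (the joints pinned at 0 and 1) distort the
  pair means; the alternative order is available via
  `reduce_pairs(..., normalize_first = TRUE)`;
* a constant raw profile maps to all zeros rather than 0/0.

Profiles are compared with Spearman correlation (average ranks on ties,
asymptotic two-sided p — appropriate when ties are possible),
agglomerative clustering under Ward's criterion on Euclidean distances,
and classical (Torgerson) multidimensional scaling into 3 dimensions.
Ward and classical MDS were chosen over alternatives (e.g. iterative
stress majorisation) because both are deterministic: merge tables and
embeddings are bit-reproducible, and ties in the agglomeration are
broken deterministically towards the lowest cluster indices. Heights are
on the distance scale (two singletons merge at their Euclidean
distance), matching `hclust(method = "ward.D2")`, against which the
implementation is cross-checked.

# The synthetic cohort generator

Real free-dance mocap corpora are typically shareable only on request,
so the package ships a generator whose *stated world* is fixed and
documented here, and every recovery claim in the test suite is relative
to it.

Each dancer is a 20-joint rest skeleton (≈ 1.7 m, per-dancer
anthropometric jitter: global scale sd 3%, per-joint jitter sd 8 mm)
animated by a bank of 3–8 oscillators per joint with frequencies drawn
from 0.5–4 Hz (the tempo range of dance movement), amplitudes scaled by
body region (≈ 30 mm at the core to ≈ 160 mm at the fingers). Each
recording is placed at a random position and heading in capture space,
and markers get 5 mm additive Gaussian noise; the root and head joints
are expanded into 2- and 3-marker clusters so the marker-averaging stage
is genuinely exercised.

Targets are encoded by **phase coupling**. A target with joint subset
*S* and coupling weight
`w = clip(base + effect_size · (label − 3) + gender_effect · male, 0, 0.95)`
adds to every joint in *S* a component
`A_c (w · shared tone + (1 − w) · own tone)` with `A_c = 120` mm. The
shared tone cancels exactly in between-joint differences, so the
expected squared distance between coupled joints scales as (1 − w)² —
nearly deterministically, because the idiosyncratic tones sit at
distinct frequencies and are close to orthogonal over a recording.
Correntropy between coupled joints is therefore monotone in the label,
which is what makes the recovery tests meaningful rather than circular:
the generator manipulates phase coherence, and the pipeline measures a
kernel similarity that responds to it. Gender additionally scales the
skeleton by 5% per unit of `gender_effect`, mimicking average
anthropometric differences.

Defaults (60 dancers, female fraction 41/58, 4 stimuli × 30 s at 60 Hz,
`effect_size = 0.25`, `gender_effect = 1`, `coupling_base = 0.4`) were
chosen once as a desk-scale cohort: large enough for stable 5-fold
decoding, small enough that the full acceptance suite stays within a few
minutes on one CPU. Extraversion and conscientiousness are coupled by
default (head/shoulder/elbow/hip/knee and head/shoulder/knee
respectively); openness, agreeableness and neuroticism are deliberately
left uncoupled so embedded and non-embedded targets can be contrasted.
The twelve genre preferences are noisy linear functions of the traits
(fixed, loosely literature-inspired loadings; noise sd 0.5, clipped to
[1, 7]) and never enter the kinematics — preference decodability arises
only transitively through the traits, which is itself a tested property.

What the generator does **not** emulate: biomechanical constraints
(joints can interpenetrate; bone lengths are only statistically
plausible), tempo-locked or stimulus-specific movement, non-stationarity
within a recording, soft-tissue artefacts, marker swaps or occlusions
(gap handling is tested with synthetic gaps instead), and any real
cohort's summary statistics. A green recovery test therefore establishes
that the pipeline correctly extracts the kind of signal the generator
plants — phase coupling and scale differences under realistic noise —
not that real dance data carries that signal at any particular strength.
In particular, the headline accuracies published for real cohorts
(e.g. gender classification above 96%, trait R² up to 0.90) are not
reproducible from synthetic data and are nowhere asserted by this
package's tests.

# Numerical choices and degenerate inputs

* Correntropy distances are clamped at 0 before exponentiation; the
  matrix is symmetrised and its diagonal set to exactly 1 to absorb
  floating-point asymmetry from the Gram-matrix computation.
* `vectorize_lower()` refuses matrices asymmetric beyond 1e-8.
* Hip joints coincident in the horizontal plane make the local rotation
  undefined and are an error, not a silent fallback.
* The SVM stopping tolerance (1e-5) is the L-BFGS projected-gradient
  bound; the evidence fixed point iterates to relative 1e-8 with a cap
  of 300 iterations.
* Sub-seeds for cohorts derive from the single spec seed by a modular
  mixing function kept below 2^31, so any recording is reproducible in
  isolation and every artifact is a pure function of (config, seed).

# Known limitations

* The marker-to-joint correspondences of published capture layouts are
  only partially specified in prose; the default map encodes the
  explicitly described derivations and passes single markers through
  otherwise. Other layouts are supported via the plain-text map
  configuration.
* PCR settings beyond the variance rule, and the SVM's cost parameter,
  are package choices, exposed as arguments.
* Sample-level random CV is retained as the default for fidelity to the
  standard protocol, with its leakage caveat documented above;
  participant-grouped CV is the mode to trust for generalisation claims.
* The CLI's `importance` output is produced by the `decode` subcommand
  (weights never exist without a decode run), so there is no separate
  `importance` subcommand.
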