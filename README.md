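# kinedecode

Decoding gender, Big-Five personality traits and musical-genre preferences
from full-body motion capture of free dance.

## The problem

When people dance freely to music, socially relevant information — gender,
personality, even what music they like — is encoded in how their joints
move relative to one another. `kinedecode` implements a complete analysis
pipeline for optical motion-capture recordings of free dance:

1. **Preprocessing** — marker trajectories (wide TSV, millimetres) are
   gap-filled, trimmed to the stimulus window, reduced to a 20-joint
   skeleton by marker averaging, and expressed in a root-centred local
   coordinate frame (the pelvis-centre joint is the per-frame origin and
   the hip-to-hip line defines the mediolateral axis), so features depend
   only on movement *within* the body, not on where or which way the
   dancer stood. Instantaneous velocity is available through two
   estimators: time differentiation followed by a zero-phase 2nd-order
   Butterworth low-pass at 24 Hz, or a Savitzky–Golay derivative filter
   (window 7, polynomial order 2).
2. **Movement features** — for the `D = 3 × 20 = 60` univariate coordinate
   series, pairwise *correntropy*, a Gaussian-kernel nonlinear analogue of
   covariance:

   `K(x_i, x_j) = exp( −‖x_i − x_j‖₂² / (2 σ² T²) )`

   with bandwidth `σ = 12.0` (millimetre scale) and `T` the series length.
   The strictly lower triangle of the symmetric 60 × 60 matrix, enumerated
   row-major, gives a feature vector of length **1770** per (dancer,
   stimulus).
3. **Decoding** — 5-fold cross-validated linear models: a linear SVM
   (squared-hinge / L2 penalty, stopping tolerance 1e-5) classifies
   gender; Bayesian linear regression (evidence-maximised Gaussian prior,
   with per-sample predictive uncertainty) and principal-component
   regression predict the five traits (1.0–5.0 scale) and twelve STOMP-R
   genre preferences (1.0–7.0 scale), scored by R² and RMSE.
4. **Joint Importance** — the absolute weights of the 1770 feature
   elements are attributed to the joints whose coordinate pairs generated
   them, summed across the 5 fold models, min-max normalised into a
   length-20 profile, and reduced to 12 pair-averaged joints (left/right
   pairs merged). Profiles are compared across targets and datasets with
   Spearman correlations, Ward-linkage agglomerative clustering, and 3-D
   classical multidimensional scaling.
5. **Synthetic cohorts** — because the motion-capture datasets this kind
   of analysis is run on are typically not public, a seeded generator
   produces full cohorts (trajectory TSVs, labels, ground truth) in which
   inter-joint phase coupling encodes gender and selected traits, and
   preferences load linearly on traits. Every recovery property of the
   pipeline is testable against known ground truth.

## Worked example

Forty synthetic recordings (20 dancers × 2 stimuli, 10 s at 60 Hz),
decoded end to end:

```r
library(kinedecode)

spec  <- synthetic_cohort_spec(n_dancers = 20, n_stimuli = 2,
                               duration = 10, sampling_rate = 60, seed = 42)
data  <- cohort_dataset(spec)          # synthesise -> joints -> features
data
#> <labeled_dataset> 40 samples (20 participants) x 1770 features; 5 traits, 12 preferences

gender <- crossval_experiment(data, "gender", "svm", make_folds(40, 5, 42))
gender$evaluation
#> <classification_evaluation> gender (svm, 5-fold): mean accuracy = 0.900

folds <- make_folds(40, 5, 42, groups = data$sample_ids$participant)
extra <- crossval_experiment(data, "extraversion", "bayesian", folds)
extra$evaluation
#> <regression_evaluation> extraversion (bayesian, 5-fold): mean R2 = 0.626, mean RMSE = 0.658

joint_importance(extra$models, target_name = "extraversion")$paired12
#> <joint_importance_profile> extraversion [paired12, d1]
#>     root    torso     neck     head      hip     knee    ankle      toe
#>    0.220    0.477    0.316    0.335    0.946    0.690    0.000    0.121
#> shoulder    elbow    wrist   finger
#>    0.868    1.000    0.534    0.585
```

The generator couples extraversion to the head–shoulder–elbow–hip–knee
chain, and exactly those joints dominate the recovered importance profile
(elbow 1.00, hip 0.95, shoulder 0.87, knee 0.69); an uninformative joint
(ankle) is pinned at 0 by the min-max normalisation. Gender is classified
at 90% on this deliberately small cohort and near-perfectly at the default
scale (60 dancers × 4 stimuli). The grouped-by-participant fold mode used
for the regression keeps stimuli of one dancer on one side of each split —
see the methods vignette for why that matters.

A command-line interface covers the same ground:

```sh
exec/kinedecode simulate --out cohort/ --seed 1 --dancers 10 --stimuli 2
exec/kinedecode run-all  --config run.json --out results/
exec/kinedecode compare  --profiles a/profiles.csv,b/profiles.csv --out cmp/
```

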