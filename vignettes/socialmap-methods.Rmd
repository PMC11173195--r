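---
title: "Methods: simulating and decoding social-concept fMRI experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding social-concept fMRI experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialmap)
```

## The problem this package addresses

How the brain represents social knowledge — the traits we attribute to
other people — can be probed by presenting trait-concept definitions in
the scanner and asking whether two organizing dimensions, *affect*
(whether a trait explicitly involves emotion) and *social desirability*
(how likable the trait is), can be read out from distributed activity
patterns. The canonical analysis stack for such questions combines
searchlight multivoxel pattern analysis (MVPA), permutation-based group
inference with threshold-free cluster enhancement (TFCE), and
representational similarity analysis (RSA) against a language-model
feature space, plus behavioral statistics on concept ratings.

`socialmap` implements that full stack together with a synthetic-data
generator that emulates the event-related design end to end. Every
analysis stage can therefore be exercised against data whose ground
truth (where signal was implanted, how strong, with what
representational structure) is known exactly, which is how the package
tests itself: null calibration on zero-signal data and parameter
recovery on implanted signal.

## The simulated experiment

The generator emulates a design with 36 trait concepts in a balanced
2×2 factorial (9 concepts per affect × desirability cell), presented
once per functional run in a run-specific random order across 8 runs.
A trial is a 0.25 s fixation, 0.5 s blank, 3.5 s audio definition and a
2 s mental-simulation period. The interval between one definition's
offset and the next definition's onset is jittered on 6–8 s in 0.5 s
steps following a pseudo-exponential distribution: 50% at 6 s, 25% at
6.5 s, 12.5% at 7 s, halving per step. The residual mass
(6.25%) is assigned to the final 8 s bin so the distribution sums
to one; this tail renormalization is our convention, as only the
leading proportions and the 6–8 s range are constrained by the design.
A deterministic largest-remainder allocation mode is also provided; it
reproduces the proportions exactly whenever they divide the trial
count.

Acquisition defaults mirror the emulated protocol: TR 0.85 s, 537
volumes per run, 2.4 mm isotropic voxels. The default grid is 24³
voxels with an ellipsoidal brain mask — large enough for 4-mm sphere
geometry while keeping simulations desk-scale; most tests shrink it
further (10³–12³).

BOLD synthesis is `baseline + HRF-convolved stimulus boxcars × implanted
patterns + linear drift + i.i.d. Gaussian noise`, with optional Gaussian
smoothing. The HRF is the canonical double-gamma (response delay 6 s,
undershoot delay 16 s, unit dispersions, 1:6 undershoot ratio), sampled
at TR resolution. The analysis side never assumes an HRF — it averages
raw signal in a peri-peak window — so the HRF matters only for
synthesis realism. Implanted multivoxel patterns are fixed per
simulated subject and consistent across runs, since cross-run decoding
presumes stable patterns; they can be drawn per class (for decoding
recovery) or per concept (for RSA recovery). Ratings are simulated with
a shared subject-by-concept true score plus independent session noise,
clipped to the 0–100 scale (clipping is logged rather than resampled —
simpler, and negligible at the default variance mix).

## Example preparation

Preparation follows the narrative order of the emulated protocol:

1. drop the first 10 volumes (steady-state magnetization),
   re-referencing onsets by −10×TR;
2. remove invariant voxels — a voxel is kept only if its temporal
   variance is positive in *every* run;
3. detrend and z-score each voxel time series per run. We fit a single
   linear model (intercept + slope) and standardize the residual, i.e.
   detrend-then-z-score in one pass; the alternative order is
   indistinguishable up to scaling and our choice is documented here;
4. average, per trial, all volumes whose *acquisition midpoint*
   `(i − 0.5) × TR` falls in the half-open window
   `[onset + 5.5, onset + 10.5)` s, then stack runs.

The midpoint/half-open inclusion rule is our convention; only the
5.5–10.5 s bounds are dictated by the emulated protocol (they bracket
the hemodynamic peak after a 3.5 s definition). Eight runs × 36
concepts yield 288 examples, 144 per class on each binary dimension.

## Searchlight decoding

Spheres of radius 4 mm (19 voxels on an interior 2.4 mm grid) are
evaluated at every in-mask voxel, with membership measured
centre-to-centre in millimetres through the affine so anisotropic grids
are handled. Within a sphere:

* features are standardized with training-set parameters only;
* a linear support-vector classifier (margin penalty C = 1, the
  conventional default) is wrapped in a sigmoid probability-calibration
  stage. No calibration settings are dictated by the emulated protocol,
  so we use Platt scaling fitted on out-of-fold decision values from a
  3-fold internal split — the standard construction. Note the sigmoid
  is monotone, so ranking metrics are essentially insensitive to it; it
  is included for protocol fidelity;
* test-set probabilities are scored with ROC AUC;
* a dummy classifier that ignores the features and emits uniform-random
  probabilities is run under the *same* folds and per-sphere seed, and
  its mean AUC (centred on 0.5) is subtracted. Pairing real and dummy
  runs seed-for-seed is our choice; it removes fold-composition noise
  from the difference.

Three cross-validation schemes are first-class: 100× stratified 80/20
shuffles (which deliberately ignore run structure, reproducing the
emulated protocol's primary scheme), leave-one-run-out, and
leave-two-concepts-out (one concept per class held out, 18 × 18 = 324
candidate folds). The two leakage-safe schemes are surfaced as
equal-status alternatives precisely because the stratified scheme can
mix trials from one run across train and test.

One master seed fans out deterministically to per-sphere sub-seeds, so
results are invariant to traversal order and to restricting the
computation to a subset of centres.

## Group inference

Subject maps (AUC minus chance, or RSA z minus chance) enter a
one-sample, one-sided sign-flip permutation test. The statistic is the
TFCE of the across-subject mean map with the standard published
parameters: height exponent H = 2, extent exponent E = 0.5, threshold
step `dh = max/100`, 26-connectivity. The null is the distribution of
the *maximum* TFCE score under random per-subject sign flips, giving
weak family-wise error control by construction; corrected p-values use
the `(1 + b)/(1 + n_perm)` convention so p can never be zero and never
falls below `1/(1 + n_perm)`. A variance-normalized variant (one-sample
t map before TFCE) is available but off by default, since
difference-from-chance maps are fed directly in the emulated protocol.
Comparing decoding of the two dimensions is implemented as a paired
difference (same subjects, a − b maps into the same machinery); the
design leaves the pairing unstated, and paired differences are the
natural choice when both maps come from the same subjects.

Calibration is verified empirically: on zero-signal experiments
(10 subjects, 12³ grid, 200 permutations, 20 replicates — sizes chosen
to keep the check desk-scale) the family-wise false-positive rate falls
inside the central 95% binomial band around the nominal 5%.

## Representational similarity analysis

Representational dissimilarity matrices (RDMs) use 1 − Pearson
correlation; vectorization uses the strict upper triangle (no
diagonal). Sphere RDMs are compared to a model RDM with Spearman rank
correlation (average ranks for ties) and Fisher-z (arctanh)
transformed, with |rho| clipped at 1 − 10⁻⁷ to keep z finite. The
empirical chance level shuffles the concept-row assignment before the
comparison; since row shuffling equals a joint row/column permutation
of the sphere RDM, each sphere's RDM is computed once and re-indexed
per shuffle. The chance map is the *mean* z over shuffles (100 by
default) — the aggregator is our choice, as only "empirical chance
level" is specified — and inference operates on observed − chance.

Noise ceilings bound attainable sphere-level RSA performance: the lower
ceiling correlates each subject's RDM with the mean RDM of the
remaining subjects, the upper ceiling with the mean including the
subject itself; both are averaged over subjects and mapped to sphere
centres.

Encoding-based RSA adds a leave-one-subject-out ridge regression from
sentence features to voxels. The L2 penalty is selected from the grid
{0.01, 0.1, 1, 10, 100, 1000} (no grid is dictated; this spans five
orders of magnitude around unity) by an inner leave-one-subject-out
search scored with the mean per-voxel Pearson correlation between
predicted and held-out responses — the inner scoring criterion is
likewise our documented choice. Features are standardized on the
training set. Voxels are split into 20 contiguous chunks fitted
independently; ridge is column-separable, so chunked and unchunked
predictions are numerically identical (asserted in tests), making
chunking purely a memory device. The held-out subject's data never
touches fitting or penalty selection, which a dedicated test audits by
corrupting the held-out data and asserting an unchanged fit.

## Language-model features

Sentence features follow the transformer-extraction contract: per-token
hidden states from a configurable layer (default 8), flattened
token-major and right-padded with zeros to 21 tokens × 768 dimensions
= 16 128 elements. Zero-padding (rather than truncation or repetition)
is our choice for sentences shorter than the maximum; only the
flattened length is constrained. Real model weights are never bundled:
the backend is a plugin function, and the shipped stub backend is a
deterministic arithmetic hash, so the package builds and tests fully
offline. Decoding in feature space uses pair-holdout cross-validation
(one fold per cross-class item pair) and a label-shuffling permutation
test with the same `(1 + b)/(1 + n_perm)` convention.

## Behavioral statistics

Paired and pooled two-sample t tests report the within-subject effect
size `d_z = t/√n` (an exact identity) and Cohen's d respectively.
Evidence is summarized by the Jeffreys–Zellner–Siow Bayes factor — a
Cauchy prior (scale √2/2) on the standardized effect, evaluated by
adaptive quadrature on the log scale and cross-checked in tests against
a fine-grid trapezoid oracle. We interpret reported "logBF10" values as
*natural* logarithms: the printed values for the emulated study's t
statistics match `ln BF10` under the default prior scale to two
decimals, whereas base-10 logs would be ~2.3× smaller. Test–retest
reliability uses the two-way random-effects, absolute-agreement,
single-measure intraclass correlation — ICC(A,1) — with an F-based 95%
confidence interval; the ICC variant is not dictated, and ICC(A,1) is
the standard choice when sessions are crossed with items and absolute
agreement (not just consistency) matters.

## Numerical choices and degenerate inputs

* Voxels with zero residual variance after detrending are zeroed and
  flagged, not dropped, so geometry is preserved.
* Constant pattern rows make correlations undefined: `compute_rdm()`
  refuses them; searchlight spheres containing one are masked `NA`.
* Folds whose training set is single-class are skipped with a warning.
* Spearman ties use average ranks; z-clipping at 1 − 10⁻⁷.
* p-value conventions everywhere use the +1/+1 form.
* Ratings are clipped to [0, 100] with the clipped count recorded.

## What the synthetic generator does and does not show

The generator reproduces the design structure (factorial labels, jitter
distribution, trial timing, run structure), hemodynamics at the level
of a canonical HRF, stable multivoxel patterns, drift and white noise.
It does *not* model physiological noise (cardiac/respiratory), head
motion, spatial autocorrelation beyond optional Gaussian smoothing,
between-subject anatomical variability (all simulated subjects share
one grid, so no spatial normalization step exists), or realistic
language: definitions are placeholders and the stub feature backend is
arithmetic. Passing recovery and calibration tests therefore shows the
*analysis machinery* is correct and calibrated under the stated noise
model — not that any particular real dataset would yield the same
brain maps.

## Problem sizes used by the test-suite

Simulations are scaled to what the checks need: 10³–12³ grids, 2–4
runs, 3–10 subjects, 50–200 permutations and 20 replicates for the
FWER check. These sizes are the package's own choice of desk-scale
verification conditions; all defaults remain at the full emulated
protocol (24³ grid, 8 runs, 100 shuffle repetitions, 10 000
permutations).

## A minimal end-to-end run

```{r, eval = FALSE}
cfg <- default_pipeline_config()
cfg$experiment$n_subjects <- 4L
cfg$experiment$grid_shape <- c(12L, 12L, 12L)
cfg$analysis$n_perm <- 200L
res <- run_pipeline(cfg, out_dir = "socialmap-demo")
cluster_table(res$group)
```

The output directory contains per-subject decoding and RSA maps
(NIfTI-1 with JSON provenance sidecars), group TFCE and corrected-p
maps, a cluster table, the behavioral report, the ratings table, and a
manifest recording the configuration hash, seeds and implanted ground
truth.
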