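---
title: "Methods: global brain connectivity mapping and multivariate pattern classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: global brain connectivity mapping and multivariate pattern classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The analysis this package implements

`gbcmvpa` re-implements, as tested R code, a resting-state fMRI analysis built
around two ideas:

1. **Voxel-wise global brain connectivity (GBC)**: for every gray-matter
   voxel, correlate its time series with every other gray-matter voxel's
   series, keep the correlations at or above a threshold (`r >= 0.25` by
   default), and aggregate them — either as the sum of Fisher r-to-z
   transformed values (the `weighted-z` variant, the default) or as a plain
   count (`binary-count` degree centrality). The map is then standardized to
   mean 0 / SD 1 over the mask ("zGBC") and smoothed with a 6 mm FWHM
   Gaussian kernel.

2. **Multivariate pattern analysis (MVPA)**: the per-subject zGBC maps are
   features for kernel classifiers — a binary linear-kernel soft-margin SVM
   (cost 1) and binary / multiclass Gaussian process classifiers — evaluated
   with leave-one-subject-out cross-validation (LOSOCV), scored with the full
   metrics suite (per-class sensitivity, specificity, accuracy, PPV, NPV,
   balanced accuracy, total accuracy, ROC/AUC for binary models), and tested
   for significance with label-permutation tests (1000 permutations by
   default; `p = count(null >= observed) / n_perm`, ties counted against the
   observed value, a zero count reported as `< 1/n_perm`).

Around this core the package provides motion quality control, the in-scope
preprocessing, discriminative-weight maps with voxel-level permutation
p-values and cluster extraction, and ROI statistics (Pearson and partial
correlation with a Bonferroni rule, summary-statistic ANOVA, voxel-wise
covariate-adjusted t maps with TFCE permutation correction).

The patient data behind the original study are not deposited, so the package
ships a **synthetic cohort generator** as a first-class, tested module: it is
the source of every dataset used by the tests and by `scripts/acceptance.R`.

## The synthetic cohort generator

`generate_cohort()` emulates the study design: four diagnostic groups
(depressed essential tremor DET, non-depressed ET, primary depression DP,
healthy controls HC; default sizes 41/49/45/43), 240 volumes at TR 2 s, an
isotropic 3 mm grid with nested ellipsoidal CSF/WM/GM compartments, subject
motion, and clinical scores.

Every gray-matter voxel's series is a weighted sum of band-limited latent
signals plus i.i.d. Gaussian noise (SD 1):

* **Background structure.** The GM mask is split into its eight octants; each
  octant shares a latent signal with a graded loading (0.7–1.8 times the base
  0.5, fixed across subjects and groups), so within-parcel correlations range
  from clearly below to clearly above the 0.25 edge threshold. Some parcels
  therefore act as connectivity hubs, and the baseline degree map carries
  stable spatial structure — as real GBC maps do. This matters numerically:
  the per-subject standardization divides by the map SD, and if baseline
  degree were flat, any planted region would dominate that SD and its
  amplitude would cancel out of the z-map.
* **Planted effects.** An `effect_spec()` names a set of GM voxels, a loading
  per group, and a band. Effect-region voxels carry the circuit latent
  *instead of* a background latent: voxels of a group with loading `L`
  correlate within the region at `L^2 / (L^2 + 1)`, while a zero-loading
  group's region is connectivity-cold. (If region voxels carried both
  latents, the added effect variance would weaken their background edges and
  the planted degree gain would largely cancel — measured, not hypothetical.)
  With the default 40-voxel regions, one-sided loadings of 0.9 and 1.1
  against 0 produce large standardized regional zGBC differences (several
  SD) at the cohort sizes used in the acceptance runs — deliberately strong,
  so reference accuracy figures act as lower bounds at any seed, and the
  moderate-versus-strong ordering is what varies between runs.
* **Latents are synthesized in the frequency domain** (random weights on the
  Fourier components strictly inside 0.01–0.08 Hz), so planted structure
  survives the band-pass exactly.
* **Subject variability.** Each subject multiplies each effect loading by
  `N(1, 0.15)`. For groups carrying a `clinical = TRUE` effect, HDRS-17 =
  `11 + 8 * subject_loading + N(0, 3)` (mean about 19 at loading 1), which
  plants a GBC–severity correlation; all other scores, and HDRS-17 in the
  remaining groups, come from group-specific normal distributions with
  clinic-typical means and SDs. Exact clinical realism is a non-goal.
* **Motion** is a random walk: per-volume increments of SD `level` (mm) on
  the three translations and `level/100` (rad) on the three rotations, first
  volume zero. The default `level = 0.05` gives mean FD around 0.17 mm —
  a typical, QC-passing subject. Determinism: one master seed spawns
  per-subject streams, so identical configs reproduce identical cohorts.

What the generator does **not** emulate: scanner physics, registration
artifacts, physiological (cardiac/respiratory) noise, anatomy, spatial
autocorrelation of noise. Passing tests therefore show that the *pipeline
arithmetic* behaves as specified and that planted effects of known size are
recovered — not that any particular clinical accuracy would be achieved on
real scans.

## Preprocessing and motion QC

In-scope preprocessing is: discard the first 10 volumes (240 → 230), then
remove nuisance structure, trends and out-of-band power. Slice-timing,
realignment estimation and spatial normalization are out of scope (synthetic
data are generated in a common space; motion parameters are simulated, not
estimated).

`clean_timeseries()` performs **one joint least-squares projection** per
voxel onto the orthogonal complement of: a constant, a linear trend, the six
rigid-body motion parameters, the global / white-matter / CSF mean series,
and all Fourier components outside 0.01–0.08 Hz. Expressing the band-pass as
regression on the out-of-band Fourier basis (rather than filtering after
regression) has three exact consequences that the tests rely on: residuals
are *exactly* orthogonal to every nuisance regressor, out-of-band sinusoids
are removed *exactly* (an in-band 0.05 Hz sine keeps more than 90 % of its
amplitude, a 0.2 Hz sine keeps essentially none), and the operation is
idempotent. Filtering after regression would re-introduce nuisance
components and make these contracts only approximate. Whether the original
analysis regressed and filtered sequentially or jointly is not knowable from
its description; the joint projection is this package's choice and is the
standard spectral-filtering-as-regression construction. A rank-deficient
regressor matrix triggers a warning and a pivoted (pseudoinverse) fit.

Framewise displacement uses the Power convention:
`FD_t = sum |Delta translation| + 50 mm * sum |Delta rotation|`, first volume
0, rotations in radians (a degrees flag is available for motion files using
that dialect). QC is count-only "scrubbing": volumes with FD strictly above
0.3 mm are flagged but never removed; a subject passes when mean FD is
strictly below 0.3 mm *and* the flagged count is strictly below 50 % of
volumes (115 of 230). All inequalities are strict, matching the stated rules.

## GBC mapping: numerical choices

* Correlations are clamped just below 1 before `atanh` so duplicated series
  cannot produce infinities.
* The threshold is one-sided (`r >= 0.25`); negative correlations never
  contribute.
* The voxel-by-voxel correlation matrix is never materialized: computation
  proceeds in voxel blocks (`block_size`, default 2048) with results
  identical to the brute-force double loop (tested to 1e-10).
* Zero-variance voxels get GBC 0 with a warning and contribute no edges.
* "Z transformation" of the formed map is interpreted as across-mask
  standardization (mean 0 / SD 1 over GM); across-subject standardization of
  single maps is not identifiable from a single subject and is not offered.
* Smoothing is separable Gaussian with `sigma = FWHM / (2 sqrt(2 ln 2))` per
  axis and **mask-aware renormalization**: the smoothed map is divided by the
  smoothed mask indicator, so values outside GM never leak in and a constant
  map is returned unchanged. Map order is fixed: compute, standardize,
  smooth.
* Whether the original degree-centrality maps summed z-values or counted
  edges is not determinable from the text; both variants are implemented
  (`weighted-z` default) behind one switch.

## Classifiers

`build_linear_kernel()` mean-centers features using **training rows only**
and returns the linear kernel of the centered rows; inside LOSOCV the
centering and every fit are recomputed per fold, so nothing about the
held-out subject reaches training (tested with a leakage sentinel).

The SVM is the standard soft-margin dual at cost 1 (the conventional default
of the MVPA toolbox the study used; exposed as a parameter). It is solved by
libsvm (`e1071`) in an exact finite-dimensional eigen-embedding of the
centered kernel — identical predictions to a precomputed-kernel solver
(cross-checked against `kernlab` in the tests) at a fraction of the cost,
which matters because permutation tests refit the entire LOSOCV thousands of
times. Fold kernels and embeddings are computed once and reused across all
permutations (the fold structure does not depend on labels).

The Gaussian process classifier is written in this package: linear covariance
plus a unit bias term, logistic likelihood, Laplace approximation (the
standard Newton iteration), predictive probabilities via the MacKay
logistic-Gaussian approximation. The multiclass version is **one-vs-rest
binary GPCs with normalized probabilities** — a documented deviation from a
joint multinomial Laplace GP, whose exact formulation in the original
toolbox is not described. Ties in predicted probability break by fixed class
order.

Metrics: per-class one-vs-rest sensitivity/specificity/accuracy/PPV/NPV;
balanced accuracy is the unweighted mean of per-class recalls (which equals
`(sens + spec) / 2` for binary problems); total accuracy is `correct/total`;
the ROC pools the n held-out scores into one curve (binary only). In a named
binary contrast ("DET vs HC") the **first** group is the class of interest:
sensitivity is its recall and positive discriminative weights mark voxels
where it has the higher GBC.

## Permutation inference

Performance: labels are permuted uniformly (unrestricted shuffles, not
stratified — the toolbox default), one permutation per repetition applied
across all folds; `p = count(null >= observed) / n_perm` exactly, with an
optional `(count+1)/(n_perm+1)` smoothed estimator off by default. Under a
permutation a training fold can become single-class; that fold predicts the
sole class rather than aborting the repetition.

Discriminative maps: per fold, the primal weights are reconstructed from the
dual coefficients, `w = X_c' alpha`, and averaged across folds (a full-sample
refit is available as an option; which of the two the original study used is
not stated). The voxel test is two-sided on |w| with the sign reported
separately, and the same permutation stream drives the performance null and
the weight null. One numerical point matters here: the raw scale of a
max-margin weight vector reflects the margin — *small* under well-separated
true labels, *large* under permuted ones — so raw-magnitude comparisons are
powerless. Observed and null maps are therefore compared at **unit L2 norm**,
making the test about where discriminative weight concentrates; a constant
(zero-variance) voxel has weight 0 and p = 1 under this rule.

Clusters: voxels with `p < 0.001` (strict) are split by weight sign, labelled
by connected components (26-connectivity default; 6/18/26 selectable), and
components with more than 30 voxels (strict) are kept, each with size, peak
|weight| voxel and centroid. The labelling is tested against an independent
igraph-based flood-fill oracle.

## ROI statistics

ROI means are plain arithmetic means of the (z)GBC map over cluster voxels.
Correlations with HDRS-17 are two-sided Pearson; the partial variant
residualizes both variables on the covariates (age, education, MMSE,
HARS-14) with `df = n - 2 - k`, reducing exactly to Pearson with no
covariates. The Bonferroni threshold implements the printed rule literally:
`alpha / (n_rois * (n_rois - 1) / 2)` — 0.05/66 for 12 ROIs — with a
conventional `alpha / n_rois` option; whether the pairwise denominator was
intentional cannot be resolved from the text, so fidelity won over
plausibility.

`anova_from_summary()` recovers the one-way ANOVA F from group means, SDs
and sizes alone and agrees exactly with a raw-data ANOVA (tested). The
voxel-wise covariate t-test fits `value ~ group + covariates` per voxel
(pooled two-sample t when the covariate set is empty). TFCE uses the
field-standard exponents E = 0.5, H = 2, step `dh = max|t|/100` (fixed across
observed and null maps of one run so scores are comparable), positive and
negative parts enhanced separately; correction is by the permutation
distribution of the image-wide maximum |TFCE| with group labels permuted and
covariates held fixed (a Freedman–Lane refit is noted as an alternative but
not implemented).

## Problem sizes and reproducibility

Tests and the acceptance script run on scaled-down cohorts: 12x12x12 grids
(488 GM voxels), 20 subjects per group for binary contrasts, 15 per group
for the four-class run, 240 volumes at TR 2 s, 1000 permutations for the
headline permutation test and a few hundred for property checks. These sizes
were chosen so the planted effects are strong and the whole suite runs in
minutes on one CPU; the statistical behaviour being tested (oracle
equalities, calibration, recovery) does not depend on the full 54k-voxel
mask. All randomness flows from explicit seeds; identical seeds reproduce
identical cohorts, fits and permutation distributions, and
`run_pipeline()` reruns byte-identically (run records keep their timestamps
in a separate file for that reason).

## Known limitations

* The multiclass GPC is one-vs-rest, not a joint multinomial Laplace GP.
* Weight maps are defined for binary models only.
* The generator's noise is white in space and time; real BOLD noise is
  neither, so absolute accuracies on synthetic cohorts are not forecasts for
  real data.
* LOSOCV with fold-wise centering is slightly pessimistic at chance on small
  null samples (a known property of leave-one-out schemes); the permutation
  test is the calibrated significance statement, and the null-calibration
  tests use bands wide enough to absorb this bias rather than hide it.
* TFCE in pure R is adequate for the package's grid sizes but would need a
  compiled labelling kernel for full-resolution masks.
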