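---
title: "White-matter functional connectivity: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{White-matter functional connectivity: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Resting-state fMRI functional connectivity (FC) is conventionally studied
between gray-matter (GM) regions, but white-matter (WM) BOLD fluctuations
also carry structured signal that correlates with the GM regions a tract
connects. `wmfc` implements a complete analysis of WM FC as a marker of
cognitive decline: it quantifies the temporal Pearson correlation between
the mean BOLD time courses of 48 deep WM tracts (an Eve-atlas style
parcellation: 21 tracts per hemisphere plus 6 commissural/midline tracts)
and 82 Brodmann GM regions (41 per hemisphere), compares these
functional-correlation matrices (FCMs) between clinical stages of
Alzheimer's disease (CN, SMC, eMCI, MCI, lMCI, ADD), relates them to
neuropsychological scores, and uses them as features for disease staging.

Three FCM kinds are assembled per subject from the full ROI correlation
matrix: `WG` (48 x 82 WM-GM, 3,936 elements), `WW` (48 x 48 WM-WM, 1,128
distinct elements) and `GG` (82 x 82, kept as a comparison baseline). The
complete WM feature set of a subject is the 3,936 WG elements plus the
1,128 WW elements: 5,064 features.

## The processing model

**ROI extraction.** Atlas label volumes are constrained by tissue
probability maps: a voxel enters an ROI's mask only if its label matches
and its tissue probability exceeds 0.8 (so partial-volume voxels near
tissue boundaries are excluded; raising the threshold can only shrink
masks). ROI time courses are unweighted voxel means, re-standardized to
zero mean and unit variance. Empty masks keep their slot so matrix shapes
never vary; their columns are `NA` and all downstream operations treat them
pairwise-complete.

**Temporal cleaning** (optional; for data that arrive as raw voxel
signals): linear detrend, ordinary-least-squares removal of the
24-parameter motion expansion (the 6 rigid-body parameters, their
one-frame-lagged copies, and both sets squared) plus the mean CSF signal,
zero-phase 4th-order Butterworth band-pass at 0.01-0.1 Hz, and voxel-wise
z-normalization. The order — detrend, nuisance regression, filter,
normalize — follows the common preprocessing sequence for resting-state
pipelines; the projection step is idempotent, and collinear nuisance
columns are dropped rather than fatal.

**Motion scrubbing.** Framewise displacement is the sum of absolute
backward differences of the six realignment parameters, rotations converted
to millimetres on a 50 mm head radius (the standard convention; the first
frame gets FD = 0). Frames with FD > 0.5 mm are censored, and the
correlation is computed on exactly the retained frames — identical, by
construction and by test, to Pearson correlation on the physically
truncated series. Subjects with fewer than 10 retained frames (a
configurable floor) are excluded and logged.

**Covariate partialling.** Each FC element is residualized across subjects
on age, sex, years of education and acquisition site (dummy-encoded,
reference dropped) by ordinary least squares. Residuals are returned plus
the element's grand mean, so group means keep a correlation-scale
interpretation; residualized values may leave [-1, 1] and are deliberately
not re-clipped. No Fisher z-transform is applied anywhere: group averaging
and testing operate on raw correlation coefficients (a z option exists but
defaults off).

## Group statistics

For each CN-vs-X contrast the element-wise statistic is the difference of
group means. Significance comes from a permutation test (default 10,000
permutations) in which group labels are shuffled jointly across elements —
preserving the dependence between elements — with the add-one correction
`p = (1 + #{|T*| >= |T|}) / (n_perm + 1)`, so p is never exactly zero.
Multiplicity is controlled by Benjamini-Hochberg step-up FDR over all
elements of the matrix under test; display matrices zero exactly the
elements with adjusted p above 0.05. Effect sizes are Cohen's d with pooled
SD.

Tract-wise FC averages each WM tract's row: over its 82 GM partners (WG) or
its 47 distinct WM partners (WW; the unit self-correlation is excluded by
default because including a constant 1 would bias every mean upward — an
inclusive variant sits behind a flag). Tract-wise values are compared by
two-sided pooled-variance t-tests (Welch behind a flag) with conventional
star coding.

The overall-FC of a subject is the mean over all elements of one FCM kind.
Group means and SDs of overall-FC are normalized by the single affine map
sending the CN mean to exactly 1 and the ADD mean to exactly 0; the same
map is applied to every group's mean and SD, so ordering and relative
spacing are preserved exactly. The same normalization can be applied to
neuropsychological scores for trend plots on a common axis.

## FC-behavior association

Element-score associations are Pearson correlations across subjects with
pairwise-complete missing-data handling, FDR-adjusted per score over that
score's full element family (not pooled across scores), and zeroed for
display where the adjusted p exceeds 0.05. Tract averages are taken over
the zeroed matrices (the raw ones remain available). Score prediction uses
random-forest regression after the same cumulative feature-selection
protocol as classification (regression criterion: cross-validated MSE),
evaluated strictly on out-of-fold predictions from 10-fold CV. R^2 is by
convention the squared Pearson correlation between true and out-of-fold
predicted scores (`r2_method = "variance"` gives 1 - SSE/SST instead); a
construction test verifies that a leaking variant (train-on-test) inflates
R^2 on null data while the out-of-fold estimate stays near zero.

## Staging classifier

Feature selection: a 200-tree random forest provides out-of-bag permutation
importance (the drop in OOB accuracy when a feature's values are shuffled);
features with non-positive importance are dropped, the survivors are sorted
by descending importance (stable ties), and cumulative sets grown five at a
time (plus the final remainder) are scored by 10-fold cross-validated error
of the downstream classifier; the smallest set achieving the minimum error
wins. A `max_size` cap on the curve (default unbounded) bounds cost when
thousands of noise features receive small positive importance; validation
runs cap at 40-60.

The classifier is an RBF-kernel SVM. C (0.1, 1, 10, 100), gamma (0.1/d,
1/d, 10/d for d features) and the disease-class misclassification penalty
(1, n_ctrl/n_dis, 2 n_ctrl/n_dis — counteracting class imbalance) are
tuned by stratified 10-fold CV on 0/1 error. Out-of-fold decision values
are pooled into a single ROC curve; AUC is the trapezoidal area and the
sensitivity/specificity operating point is chosen by Youden's J (the
threshold rule is a package convention, recorded in the output). Staging
proceeds over cumulative contrasts: CN vs ADD; vs lMCI+ADD; vs
MCI+lMCI+ADD; vs eMCI+MCI+lMCI+ADD; vs SMC+eMCI+MCI+lMCI+ADD.

By default the *entire* protocol — importance, selection, tuning — is
nested inside an outer 10-fold CV, so the reported ROC is an honest
generalization estimate; `nested = FALSE` reproduces the simpler classical
protocol (select and tune once on all subjects, report the final model's CV
ROC), which is optimistic at small n and provided for comparability.
Whether pooled-out-of-fold or fold-averaged ROCs are reported is a genuine
convention choice; pooling was chosen and is recorded in the result object.

## The synthetic cohort generator

Because the motivating clinical data are access-restricted, every stage is
validated on a fully synthetic cohort with known ground truth. Per subject,
ROI time series are drawn from a zero-mean stationary multivariate Gaussian
model (via the Cholesky factor of the group's target correlation matrix;
optional AR(1) temporal autocorrelation, default off), so the population
correlation equals the target exactly and the empirical correlation
converges to it at the usual `(1 - r^2)/sqrt(n)` rate — the basis of the
planted-effect fidelity tests.

The base structure is equicorrelation at `base_correlation` (default
0.35, a typical mean resting-state ROI correlation). Deficits are planted
per group. The default mechanism is **tract-signal attenuation**: the WM
tracts named in the deficit edge set have their shared-signal loading
scaled so each affected tract's correlation with an unaffected partner
drops by exactly the group's delta; pairs of affected tracts drop slightly
further. This construction is positive semi-definite for any delta in
`[0, base]` and concentrates the deficit on named tracts — the horizontal
stripe pattern that tract-wise statistics are designed to detect. A
subtractive mode that lowers exactly the listed edges is available for
sparse edge sets; it is backed by an eigenvalue-clipping PSD repair that
refuses to distort any entry by more than 0.05. The subtractive mode
cannot represent dense planted blocks (a 5-tract x 20-partner block at
delta 0.25 has no valid correlation matrix with an otherwise-flat
background — its repair would move entries by ~0.16), which is why
attenuation is the default.

The default study conditions mirror a 6-stage cohort with pronounced
deficits only late: group sizes (CN 60, SMC 18, eMCI 33, MCI 15, lMCI 18,
ADD 35) scale the motivating cohort's proportions to desk size with the
CN/ADD pair at full strength for the staging analyses; deltas (0, 0.03,
0.04, 0.06, 0.15, 0.30) are free parameters of the simulation — the
clinical literature does not report per-edge effect magnitudes — chosen so
late stages are clearly detectable and early stages are not, matching the
qualitative pattern the analysis targets. 200 frames at TR 3 s emulate a
typical single resting-state run.

Motion tables carry slow random-walk drift plus spikes (rate 0.03/frame): a
sustained 0.6 mm translation step, so the backward-difference FD exceeds
the 0.5 mm threshold at exactly the spike frame, and an additive artifact
across all ROIs at that frame, so censoring genuinely matters.
Neuropsychological scores are affine in the group's true overall FC
(anchored at published-scale CN and ADD group means, e.g. MMSE 29.1 to
22.4) plus Gaussian noise with plausible clipping bounds; the Hachinski and
GDS scales are generated FC-independent, emulating their expected null
associations. Covariates (age, sex, education, site) are drawn from
realistic ranges but do not influence the series; the partialling stage is
validated separately against closed-form least squares.

What the generator does *not* emulate: hemodynamic response functions,
scanner noise spectra, spatial smoothness, distance-dependent motion
artifacts, or site effects on FC. Passing tests therefore demonstrate that
the statistical machinery recovers truth under its stated model, not that
the pipeline is robust to every artifact of real acquisitions.

## Numerical choices and degenerate inputs

- Permutation p-values use the add-one correction; n_perm below 100 warns.
- BH adjustment preserves matrix shape and is exactly `stats::p.adjust`.
- Zero pooled SD yields `NA` effect sizes; constant scores yield all-`NA`
  association rows; empty ROI masks yield `NA` columns handled
  pairwise-complete throughout.
- Fewer than 10 retained frames raises a typed condition
  (`wmfc_too_few_frames`) that cohort-level wrappers convert into a logged
  exclusion.
- Fold assignment is stratified by class (or by outcome quantile bins for
  regression); seeds flow from one master seed through `derive_seed()` into
  every stochastic stage, making whole-pipeline runs bit-reproducible.
- Selection tie-breaks: equal importances keep original feature order;
  equal CV errors prefer the smaller feature set.

## Validation scale

The packaged validation (testthat suite plus `scripts/acceptance.R`) uses
problem sizes chosen for a desk machine: null calibration on a 25 x 80
parcellation (2,000 null elements, 1,000 permutations); deficit recovery on
the full 48 x 82 registry (50 subjects per group, 200 frames, 100
designated planted edges, 5,000 permutations, 10 replicates); selection
recovery with 10 planted features among 500 noise features (5 seeds); and
the staging ladder on a 16 x 40 parcellation (179 subjects, 760 features,
fully nested CV). These sizes are the package's validation design; all of
them can be scaled up through the same interfaces.

## Known limitations

- The Gaussian stationary signal model has no hemodynamic or physiological
  structure; calibration under realistic autocorrelation should be checked
  with `ar_coefficient > 0` for serious use.
- The GUIDE split criterion used by the original staging study is not
  available in R's random-forest implementations; standard CART splitting
  with permutation importance is used instead.
- Attenuation deficits necessarily lower *all* edges of an affected tract;
  arbitrary per-edge deficit patterns are limited by positive
  semi-definiteness of correlation matrices (see above).
- Residualized FC values may leave [-1, 1]; downstream consumers that
  assume bounded correlations should use the un-partialled stacks.
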