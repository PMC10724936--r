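---
title: "Methods: ensemble assessment of coronary lesion significance from OCT lumen profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble assessment of coronary lesion significance from OCT lumen profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octffr)
```

## The problem

Intermediate coronary stenoses are graded functionally by fractional flow
reserve (FFR), the ratio of the pressure distal to the lesion over the
aortic pressure at maximal hyperemia; FFR at or below 0.8 marks a lesion as
hemodynamically significant and an indication for revascularization. FFR is
invasive and costly, and a large share of measured lesions fall in the
clinical *gray zone* (FFR in [0.75, 0.85]) where the decision is genuinely
uncertain. This package implements a pipeline that predicts the binary FFR
label from intravascular optical coherence tomography (OCT) lumen geometry
and routine clinical covariates: geometric feature extraction from a 1-D
lumen radius signal, drift correction of the pressure ground truth,
univariate base-learner ranking, and an ROC-cutoff voting ensemble — plus a
calibrated synthetic cohort generator standing in for the private
single-center dataset (80 patients, 102 lesions) the original study was
built on.

## Ground truth: drift correction and labeling

At the end of an FFR pullback the wire and catheter pressures should
superimpose; a residual offset `D` (drift) biases the recorded distal
pressure. The pipeline corrects `Pd` by plain signed addition,
`corrected_Pd = Pd + D`, and computes `corrected_FFR = corrected_Pd / Pa`.
Although drifts of 1–2 mmHg are often accepted as insignificant in
practice, the correction is applied exactly for drift magnitudes in
{2, 3} mmHg, matching the source study's protocol (12 lesions at 2 mmHg, 3
at 3 mmHg, 15 adjusted in total out of 102); a drift beyond 3 mmHg means
the measurement itself should have been repeated, so `corrected_ffr()`
warns rather than silently correcting. The label rule is inclusive at the
cutoff: FFR exactly 0.8 is class 1 (significant). Gray-zone bounds are
inclusive on both ends and configurable; the subgroup analysis uses the
narrower decision zone [0.75, 0.83].

Negative drifts are not described in the source protocol; when a negative
drift magnitude falls in the relevance set, the signed addition is applied
and a warning is raised, so the choice is visible rather than silent.

## Geometric features

Each lesion's input is a 1-D lumen radius signal sampled at 5 frames/mm
(0.2 mm spacing, stored per profile), with expert-annotated frame markers
for the analyzed segment and the stenosis. Twelve features are computed
with one stated convention: frame indices are 0-based, interval lengths use
`(end − start) × spacing`, means are over inclusive frame ranges, and the
proximal/distal reference radii are the radii at the annotated lesion
boundary frames. Notable formulas: percentage diameter reduction
`100 (1 − 2 r_mean / (r_prox + r_dist))` (note it uses the *segment mean*
radius, not the minimum — it coincides with the radius rapport
`((r_prox + r_dist)/2 − r_min) / ((r_prox + r_dist)/2)` only when
`r_mean = r_min`), maximum radius rapport `(r_max − r_min)/r_max`, and the
proximal/distal areas `π r²`.

The full matrix has 26 columns: the 12 geometric features, the
physician-annotated minimal lumen diameter (MLD — deliberately distinct
from `2 × r_min`, since the annotation and the automatic signal disagree in
practice), and 13 clinical covariates. Assembly refuses missing values by
naming the lesion and column; nothing is imputed.

**Normalization.** The matrix is L1-normalized *per feature column* (each
column divided by the sum of its absolute values). A per-row alternative
would mix units (mm, years, percent) across features and destroy the
meaning of univariate models, so the column convention was adopted; since
the normalization is a positive affine rescale per column it changes no
Pearson correlation, no ROC, and no rank-based quantity.

**Collinearity pruning.** Pairs with |Pearson r| at or above 0.999 are
reduced by keeping the earlier feature in an explicit rank order
(`prune_perfectly_correlated(..., rank_order = )`). The threshold is 0.999
rather than exact equality because "perfect" empirical correlation is a
floating-point statement. On real data the published final top-5 feature
list keeps percentage diameter reduction and drops radius rapport, so the
rank order passed on real runs should place percentage diameter reduction
first; on the synthetic cohorts the raised-cosine stenosis shape keeps the
pair's correlation high but below 0.999, and nothing is pruned.

## Univariate models and validation

Twelve base learners are registered: SVMs with linear, degree-3 polynomial
and RBF kernels (features standardized inside the fit, gamma = `1/d` on the
unit-variance columns — the "scale" convention), a
decision tree, kNN (k = 5), random forests with 20/40/60/100 trees,
discrete AdaBoost over decision stumps, Gaussian naive Bayes, and logistic
regression. The source study names the families and one tree count; the
remaining counts and hyperparameters are this package's declared defaults,
chosen to total twelve, not inferred as the original authors' choices.
AdaBoost is written out in the package because no dependency provides the
classical stump-boosting algorithm; SVMs, trees, forests and naive Bayes
go through e1071, rpart and randomForest.

Two validation protocols are used, both grouped at the patient level so
that no patient's lesions are split across training and test:

* **Tenfold accuracy study** (feature ranking): stratified patient-grouped
  tenfold CV repeated over 10 seeds; the per-feature, per-learner mean/sd/
  max/min accuracies are summarized and each feature keeps its best
  learner (ties: lower sd, then registry order). Features whose *mean*
  accuracy reaches 60% survive; applied to the published per-feature
  table, this rule — and only this rule among the printed columns —
  reproduces the published top-14 cut, which is why "maximum accuracy of
  60%" is read as a mean-accuracy bar.
* **Leave-one-patient-out** (ensemble inputs): one fold per patient (80
  folds at the study size). In every fold a threshold balancing
  sensitivity and specificity (`|Se − Sp|` minimized over score midpoints;
  ties by maximal Se + Sp, then smallest threshold; positive call at
  `score ≥ threshold`) is chosen on the training scores and applied to the
  held-out lesions, yielding an out-of-fold probability `O_i` and crisp
  label `C_i` per lesion. Degenerate folds (single-class training labels)
  are skipped with a warning, never imputed.

## ROC analysis and ensemble voting

ROC curves are enumerated over all candidate thresholds (score midpoints
plus ∓∞ sentinels); AUC is the Mann–Whitney pair-counting estimator. The
operating cutoff is the *closest-to-(0,1)* criterion — the threshold
minimizing `√((1−Se)² + (1−Sp)²)` — rather than the Youden index; ties go
to higher sensitivity, then the smaller threshold.

Votes are built three ways from the univariate out-of-fold outputs:
**M1** thresholds every model's probabilities at the *mean* of the
per-model ROC cutoffs; **M2** thresholds each model at its *own* cutoff;
**M3** votes with the per-fold-thresholded crisp labels directly (the ROC
cutoff of the mean crisp vote is computed and reported for completeness,
but the votes are not re-thresholded with it — the prose description of
this strategy is ambiguous, and this concretization is the package's
declared reading). Aggregation is either a simple majority (mean vote) or
weighted voting with log-odds weights `w_i = log(acc_i / (1 − acc_i))`
from each model's out-of-fold accuracy. Weights use the natural log and
are normalized (`Σ w_i v_i / Σ w_i`) before the 0.5 comparison, which
makes the final label invariant to the (unstated) log base and to any
positive rescaling of the weights. Accuracies are clipped to
`[ε, 1−ε]`, ε = 1e-6, so weights stay finite at 0 and 1. A score of
exactly 0.5 is called positive, erring toward detecting significant
lesions. If all models are at or below chance the weighted sum is
non-positive and the package refuses with advice to use simple voting.

An optional monotone recalibration of the probabilities was considered and
deliberately left out of the default path: every downstream quantity is
either rank-based (AUC) or thresholded per fold, so a monotone transform
cannot change the reported results.

## Reporting

Diagnostic metrics follow the standard confusion-matrix forms, reported in
percent with two decimals; zero-denominator metrics are reported as
undefined (`NA`), never NaN. Binomial proportions get Wilson score
intervals with z = 1.96 — this choice, among the common interval families,
reproduces the source study's printed bounds exactly (e.g. a sensitivity
of 38/47 gives (67.46, 89.58)). AUCs get the Hanley–McNeil closed-form
interval, which reproduces the study's flagship AUC interval to about one
unit in the third decimal; since the study does not name its method, a
stratified bootstrap would be an equally defensible alternative and the
closed form is the package default for determinism. Note two arithmetic
facts the implementation surfaces rather than hides: the Wilson interval
*does* attain 0% and 100% exactly at 0 or n successes, and the published
class counts imply 47 positives / 55 negatives even though the printed
lesion table says 48 — the reported Se/NPV denominators (38/47, 45/54)
force the former.

## The synthetic cohort generator

The generator replaces the private dataset and defines the package's study
conditions. Its defaults are fixed once:

* **Cohort structure**: 80 patients / 102 lesions (1–3 lesions per
  patient, probabilities 0.775/0.175/0.05 giving the right mean, repaired
  to the exact lesion budget), vessel mix 57/20/25 LAD/LCX/RCA, proximal
  lesions in 40% of LAD cases.
* **FFR distribution**: a mixture of zone-truncated normals on
  (0.40, 0.75) / [0.75, 0.85] / (0.85, 1.00) with masses 25/47/30 out of
  102. The base mean and sd are solved once, deterministically, inside
  `cohort_config()` so the mixture's mean and sd equal 0.80 and 0.08
  exactly (the solution is ≈ N(0.7777, 0.0810)).
* **Geometry**: healthy lumen radius by vessel (LAD 1.75 ± 0.15 mm,
  LCX 1.55 ± 0.15, RCA 1.85 ± 0.20, floored at 1.2), linear taper of
  5–25% over a 25–70 mm segment (one pullback covers at most 75 mm),
  raised-cosine stenosis of length 5–20 mm. The raised-cosine shape was
  chosen because it is smooth, two-parameter, and keeps the stenosis-mean
  and minimum radii distinct so the rapport features do not degenerate.
* **Geometry-to-FFR coupling**: the source study measures FFR and never
  models hemodynamics, so a monotone pressure-drop surrogate (viscous
  `c_v · lengthS / r_min⁴ · Q` plus turbulent expansion loss
  `c_t · (A_prox/A_min − 1)² · Q²`, coefficients at physiologic scale:
  `c_v = 0.0664 mmHg·mm³·s/mL`, `c_t = 0.22 mmHg·s²/mL²`, Q = 2 mL/s)
  links severity to FFR. Each lesion's severity is found by root-finding
  so that geometry predicts the drawn FFR up to a physiologic residual of
  sd 0.05 FFR units — the scale of the disagreement between anatomic FFR
  estimates and the wire measurement in the validation literature. With
  the residual at 0, geometry determines FFR exactly and a univariate
  model on percentage diameter reduction separates the classes almost
  perfectly; the residual is what keeps synthetic univariate accuracies
  in the realistic 60–80% band. Because the viscous term never vanishes
  for an open lumen, a severity-0 profile evaluates to FFR ≈ 0.99–0.999
  rather than exactly 1; targets above that value map to severity 0.
* **Measurement layers**: radius noise sd 0.02 mm (OCT axial-resolution
  scale), Pa ~ N(95, 8) mmHg, pressures rounded to 1 mmHg (instrument
  granularity; rounding is configurable and the inversion tests disable
  it), physician MLD = `2 r_min` + N(0, 0.1 mm), drift assigned to
  exactly the configured lesion counts. Weight and hematocrit carry a
  weak linear signal of the patient's mean FFR deficit (40 kg and 25
  percentage points per FFR unit — about +3 kg and +2% for a patient at
  FFR 0.72), reflecting the study's finding that these covariates rank
  among the informative features; all other clinical covariates are
  independent of FFR, drawn from the published population marginals.
* **Gray-zone stress option**: `gray_zone_extra_noise_sd` adds
  geometry-vs-FFR residual only inside the gray zone, used to probe that
  in-zone accuracy degrades relative to outside.

What the generator does *not* emulate: spatial correlation of OCT noise,
vessel-specific FFR distributions (the real LAD mean is lower than LCX),
plaque morphology, culprit-lesion timelines, or any true hemodynamics
beyond the monotone surrogate. Passing tests on this cohort therefore
demonstrate that the *pipeline* is implemented correctly and behaves as
the study reports directionally (ensembling helps; the gray zone is
harder); they cannot certify clinical accuracy on real OCT data.

## Numerical choices and degenerate inputs

Thresholds are always score midpoints plus sentinels, so no threshold
coincides with a score and the `≥` convention is unambiguous. All-equal
scores leave only the sentinels; the balanced threshold then returns the
smaller sentinel (−∞, call everything positive). Constant feature columns
correlate as 0 with a warning instead of NA. An all-zero column cannot be
L1-normalized and errors. Every stochastic step (fold assignment, learner
fitting, cohort draws) is seeded, and a cohort is a deterministic function
of its `cohort_config()` including the seed.

## Problem sizes used in the checks

The packaged checks run the generator at three scales, chosen as the
package's own verification budget: the study size (80/102) for structural
assertions, 500-lesion cohorts over 20 seeds for the behavioral claims
(ensemble vs best univariate, gray-zone degradation, permutation null),
and a single 50,000-lesion cohort for distribution calibration (mean
corrected FFR within 0.01 of 0.80, sd within 0.01 of 0.08, zone-mass
goodness of fit at α = 0.01). Oracle comparisons use 1,000 random
profiles for the geometric features, random score sets up to n = 50 for
ROC/AUC/cutoffs against O(n²) brute force, and 20-point sets for kNN
against a literal neighbor search.

## Known limitations

The surrogate's coefficients are a stand-in, not constrained by the source
study; absolute synthetic accuracies therefore track the noise defaults,
and only *relative* statements (ensemble ≥ univariate, gray zone harder)
transfer. The published per-feature accuracy table ships with the package
as the input to the selection-rule check, but the models behind it cannot
be refit without the private cohort. The multivariate baseline shares the
LOPO protocol but not the original's unknown hyperparameters.
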