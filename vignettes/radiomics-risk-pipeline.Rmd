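---
title: "Radiomics risk modelling for pT1 renal cell carcinoma: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomics risk modelling for pT1 renal cell carcinoma: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radrcc)
```

`radrcc` re-implements, as a composable and fully testable pipeline, a
radiogenomics analysis of post-operative metastasis risk in organ-confined
renal cell carcinoma: CT texture features over whole/core/rim tumor
regions, a bootstrap-stability-selected prognostic signature, a Cox
radiomics risk score with optimal-cutoff Kaplan–Meier stratification, and
the linkage of imaging features to gene expression. This vignette explains
the models and their assumptions, the parameters that matter, the synthetic
data the package tests itself on, and the design decisions taken where the
underlying methodology is open to interpretation.

## Region-of-interest partition

The tumor mask is split into a core ("inner") and a peripheral ("outer")
region, intended to separate the stable tumor core from the dynamically
enhancing rim. `partition_roi()` erodes the whole mask by a sphere of
radius $(1 - f)\,R_{eq}$, where $R_{eq}$ is the mask's equivalent-sphere
radius and $f$ (`inner_fraction`, default 0.5) is the fraction of that
radius the core retains. Erosion is defined in millimetres and discretized
per axis, so thick-slice CT (the generator's default spacing is
1 × 1 × 2.5 mm) erodes by fewer slices than in-plane voxels. Two
conventions are fixed deliberately:

* a positive erosion radius below the voxel pitch still erodes by the
  finest-axis neighbourhood, so a near-point lesion has an empty core and
  `outer == whole` rather than a core equal to the whole mask;
* if erosion empties the mask the partition degenerates gracefully
  (`inner` empty), and the feature extractor falls back to whole-ROI
  values for inner-family features, with a warning naming the patient.

How the original study constructed its inner/outer split (erosion,
distance percentiles, or manual) is not documented; radius-scaled erosion
was chosen because it is shape-adaptive and has a single interpretable
parameter. It is configurable end to end.

## The feature registry

`feature_registry()` freezes 121 column names:
(19 histogram + 16 GLCM + 2 ISZM) × {WHOLE, INNER, OUTER} = 111 texture
features, 8 morphology features on the whole mask, and 2 semantic HU
ratios. The published inventory pins the counts (19/16/2 per ROI, 8
morphology) and a handful of names (`INNER_Min_Hist`,
`OUTER_Energy_Hist`, `INNER_MaxProbability_GLCM`, `Under80HURatio`); the
remaining membership follows the common radiomics canon and is pinned by
the test suite, since the named signature features must exist and the rest
are interchangeable capacity.

Numerical choices, all registry-level and frozen:

* **Discretization.** Equal-width bins over the ROI's own [min, max]:
  128 bins for histogram and GLCM features, 32 for ISZM. Binned features
  are therefore invariant to a global HU shift (a property test).
* **Histogram family.** Entropy in bits over bin probabilities;
  uniformity $\sum_i p_i^2$; *energy* $\sum_i n_i^2$ over raw bin counts
  — deliberately distinct from uniformity so the 19 features stay
  distinct (whether the study's "energy of the histogram" was
  $\sum n_i^2$, $\sum p_i^2$ or $\sum x_i^2$ is unknowable from its text;
  the registry documents this choice and the tests pin it); total energy
  multiplies by voxel volume. Skewness and kurtosis are population moment
  ratios, defined as 0 for constant input so tables stay complete.
* **GLCM.** 3D co-occurrences over the 13 unique unit offsets, symmetric,
  in-mask pairs only; per-offset matrices are normalized to sum 1,
  features computed per offset and averaged over offsets with at least
  one pair. All entropies use log base 2. Degenerate conventions:
  correlation of a zero-variance matrix is 1, the first informational
  measure of correlation is 0 when the marginal entropy vanishes.
* **ISZM.** Zones are maximal 26-connected constant-level regions after
  32-bin discretization; the two features are zone percentage and the
  normalized size-zone non-uniformity. Note a parity checkerboard is
  *not* the all-singleton case under 26-connectivity — diagonal
  neighbours connect — so the degenerate tests use an all-distinct-level
  volume instead.
* **Morphology.** Volume is voxel count × voxel volume. Surface area
  comes from a triangulated iso-surface: marching tetrahedra at level 0.5
  on the mask after a light Gaussian smooth (0.8 voxel), with linear
  edge interpolation. Meshing the raw binary mask would inherit the
  voxel staircase and overestimate a sphere's area by roughly a quarter;
  the smoothed, interpolated mesh is within ~1% on digital balls of the
  generator's size range. Sphericity, compactness and the
  surface-to-volume ratio use the mesh volume (divergence theorem over
  the oriented mesh) together with the mesh area, which bounds sphericity
  by 1 via the isoperimetric inequality; elongation and flatness are
  $\sqrt{\lambda_2/\lambda_1}$ and $\sqrt{\lambda_3/\lambda_1}$ of the
  voxel cloud's principal components; the maximum 3D diameter is the
  exact largest surface-voxel distance.
* **Semantic ratios.** Strictly-under fractions of in-mask voxels below
  100 and 80 HU, reading "under 80 HU" literally: a voxel at exactly
  80 HU does not count.

## Class balancing and stability selection

The emulated study design is heavily imbalanced (46 vs 12), so
`adasyn_balance()` implements ADASYN: each minority point is weighted by
the share of majority points among its $k$ nearest neighbours (Euclidean
on z-scored features), and synthetic points are convex combinations of a
minority point and one of its $k$ nearest minority neighbours, generated
in the original feature space. Originals are always a prefix of the
output. Per-point synthetic counts are rounded, so the final balance can
be off by a couple of cases — the emulated study itself reports 47/47
from 46/12, a count its stated mechanism does not explain exactly, and no
attempt is made to reproduce that artefact.

`bootstrap_lasso_selection()` repeats, per replicate: a stratified
(1 − holdout) split without replacement (holdout 0.2; the study's
"bootstrapping with a holdout ratio" is read as repeated random splits),
per-split z-scoring, an L1 logistic fit with λ chosen by 5-fold
cross-validated minimum deviance, and a record of nonzero coefficients.
Features selected in ≥ 95% of replicates form the signature. Balancing
*before* the loop (`adasyn_mode = "global"`) matches the study's stated
order but leaks synthetic neighbours across splits; the sound
`"per_bootstrap"` variant is provided. Classifier evaluation
(`evaluate_classifiers()`) uses a ridge-regularized logistic model, a
linear-kernel SVM and a 50-tree random forest, reporting bootstrap means
of AUC/sensitivity/specificity/accuracy on train and holdout;
`logistic_importance()` reports the unpenalized multivariate logistic
weights and odds ratios ($OR = e^w$), with perfect separation detected
via boundary fitted values and weights capped at |20|.

## The radiomics risk score

`fit_rrs_model()` is a multivariate Cox partial-likelihood fit (Efron tie
handling — standard for monthly follow-up data with moderate ties) on the
*original*, unbalanced cohort; oversampled data would distort the risk
set. The risk score is the bare linear predictor
$RRS_i = \sum_f \beta_f x_{if}$ with no centering, so it is exactly
linear and monotone in each feature. `optimal_cutoff()` scans every
unique score between the 15th and 85th percentiles (the band prevents
degenerate tiny groups; the published cutoff percentiles, around 70–79%,
lie comfortably inside it), requires ≥ 3 patients per side, maximizes the
log-rank statistic and breaks ties toward the median. Because cutpoint
optimization inflates type-I error, the reported log-rank p is
optimistic; `km_logrank(n_permutations = )` offers a permutation-adjusted
p that re-runs the full search on permuted scores. The reported hazard
ratio is from a Cox fit on the binary group indicator, which is what a
published HR with CI for a two-group split implies. Validation
(`validate_rrs()`) keeps the signature names but refits weights and
cutoff on the validation cohort, mirroring the study's protocol.

## Radiogenomic linkage

`trait_gene_correlation()` screens every gene against every signature
feature by Spearman correlation, keeping p < 0.05 per gene — matching the
emulated study's stated threshold; no multiplicity correction by default,
with a Benjamini–Hochberg option (`fdr = TRUE`). P-values use the exact
permutation distribution below 10 samples and the t-approximation from 10
(the WTS cohort emulated here has 11 samples, right at the boundary);
average ranks break ties. Top-n subsets (default 100) are ranked by
|rho| — whether the original ranking was by |rho|, p, or rho within sign
is unstated; |rho| is the natural magnitude ordering. Set overlap is the
Jaccard coefficient.

The per-sample enrichment score is a rank-sum z: genes are ranked within
each sample and a set's score is the standardized sum of its members'
ranks. This is a deliberate simplification of GSVA/ssGSEA's running-sum
statistics: it is rank-based (hence invariant to any strictly monotone
within-sample transform), permutation-testable in closed form, and the
analysis uses enrichment only ordinally (low/intermediate/high
subgroups). `cluster_and_survival()` clusters samples on ES profiles
(Euclidean, Ward linkage), cuts at k = 3, orders clusters by the
unweighted mean ES over all sets — the "combined" score's weighting being
unstated, equal weights are the neutral choice — and compares the extreme
groups by log-rank.

## The synthetic cohort: what it emulates and what it does not

`cohort_spec()` fixes the study conditions: 58 patients with a 12/58
metastasis fraction, a 32³ grid at 1 × 1 × 2.5 mm, an enhancing rim
around 110 ± 12 HU with a hypodense core around 25 ± 8 HU (nephrographic-
phase levels: enhancing renal cortex well above 100 HU, necrosis below
30 HU), necrotic volume fractions of 0.10 (non-metastasis) versus 0.40
(metastasis), 50% higher rim texture amplitude in the metastasis class,
spatially correlated Gaussian noise (1.5-voxel correlation length, FFT
smoothing of white noise — the simplest field with controllable GLCM
scale), and per-patient ellipsoidal tumors with equivalent radii of
7–10 mm (small pT1a lesions that fit the grid with margin). Survival is
exponential with hazard
$h_i = h_0 \exp(\sum_k \beta_k z_{ik})$ on the four cohort-standardized
signature features, $h_0 = 0.012$/month, independent exponential
censoring at 0.010/month, and planted weights (−0.10, 0.03, 0.43, 0.64)
of the magnitudes the risk-score equation reports. The feature
distributions of the real discovery cohort are unpublished, so these
defaults are calibration-free: chosen once for clinical plausibility, not
fitted to any target.

`generate_expression()` plants signal genes as monotone (linear on the
log scale, then exponentiated to a non-negative RPKM-like scale)
functions of their feature with Gaussian noise; Spearman statistics are
monotone-invariant, so the linear link is unrestrictive. The default sign
structure gives `INNER_Min_Hist` 91% negative-sign genes and the other
features 9%, emulating the reported sign asymmetry (low core minima —
more necrosis — higher risk). `generate_signal_features()` additionally
provides a designed table of 4 class-shifted + 117 null columns for
measuring selection operating characteristics, because the image-derived
features are mutually correlated and contain no guaranteed-null columns.

Passing tests on this cohort show that the pipeline's statistics behave
as designed under their own assumptions — proportional hazards,
independent censoring, monotone gene–feature links, class-conditional
texture contrast. They do not show robustness to scanner effects,
segmentation variability, non-ellipsoidal or infiltrative growth,
non-proportional hazards, or expression covariance structure; none of
these are modelled.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed, and the pipeline derives
per-stage seeds from one global seed by stable string hashing, so each
stage is independently reproducible and bit-identical under a fixed seed.
The test and acceptance runs use sizes chosen to make their properties
measurable rather than exhaustive: oracle equivalence on ≤ 8³ volumes
(1e-10), selection recovery on the 46/12 design with 500 bootstraps and
10-seed permutation nulls with 100 bootstraps each, Cox coefficient
recovery at n = 400 (within 3 SE), a planted hazard ratio of 8 at
n = 200, null calibration of the gene screen over 200 seeds of
200 genes × 11 samples, and study-scale (n = 58) end-to-end runs with
300 bootstraps. The study-scale setting of 10,000 bootstraps remains the
`selection_config()` default for real use.

## Known limitations

* The selection loop refits `cv.glmnet` per replicate; at the study-scale
  10,000 replicates this is minutes of compute, and the frequency
  estimate's Monte-Carlo error (~0.5% at 10,000) is the practical
  resolution of the 95% threshold.
* The optimal-cutoff p-value is reported uncorrected by default (the
  permutation adjustment is opt-in), matching the emulated analysis.
* ADASYN's density weighting uses plain Euclidean distance on z-scored
  features; with 121 mostly-noise dimensions, neighbourhood weights are
  nearly uniform.
* The enrichment score is a rank-sum z, not the Kuiper-type running
  statistic of GSVA; scores are comparable across samples but not
  numerically interchangeable with GSVA output.
* Validation refits weights and cutoff on the validation cohort (as the
  emulated protocol specifies); it is a reproducibility check of the
  signature, not a frozen-model external validation.
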