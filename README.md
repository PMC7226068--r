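# radrcc

CT radiomics and radiogenomics risk modelling for early-stage (pT1) renal
cell carcinoma.

Most organ-confined kidney cancers are cured by surgery, yet a minority of
patients later develop distant metastases. `radrcc` implements, as a tested
and reusable R pipeline, the analysis used to flag those patients from
routine contrast-enhanced CT: texture features extracted over whole, core
(inner) and peripheral (outer) tumor regions, a stability-selected
prognostic signature, a Cox radiomics risk score with Kaplan–Meier
stratification, and a radiogenomic linkage of the imaging features to gene
expression. It is intended for methodologists and imaging researchers who
want to exercise, stress-test or extend this class of radiomics analysis
without access to protected patient data: a synthetic cohort generator
reproduces the statistical structure the analysis assumes (hypodense
necrotic cores, textured rims, feature-driven survival, planted gene–feature
correlations), so every stage is verifiable end to end.

## The model

1. **Features.** Each tumor mask is partitioned by spherical erosion into
   whole/inner/outer ROIs, and 121 features are computed:
   (19 histogram + 16 GLCM + 2 ISZM) × 3 ROIs = 111 texture features,
   8 morphology features, and 2 semantic Hounsfield-unit ratios
   (fraction of voxels under 100 and 80 HU).
2. **Signature.** After ADASYN oversampling of the minority (metastasis)
   class, an L1-penalized logistic regression is refitted on thousands of
   stratified bootstrap splits (0.2 holdout, penalty chosen by 5-fold
   cross-validation). Features selected in ≥ 95% of replicates form the
   stable signature; three classifiers (regularized logistic, linear SVM,
   50-tree random forest) measure its discriminative value.
3. **Risk score.** On the original (unbalanced) cohort a multivariate Cox
   model over the signature gives each patient a radiomics risk score

   *RRS*ᵢ = Σ_f β_f · x_if ,   h(xᵢ, t) = h₀(t) · exp(*RRS*ᵢ)

   A grid search over score cutoffs maximizes the log-rank statistic
   between high- and low-risk groups; the hazard ratio comes from a Cox fit
   on the binary group label. Validation keeps the signature but refits
   weights and cutoff.
4. **Radiogenomics.** Genes whose expression Spearman-correlates with a
   signature feature (p < 0.05) form its trait-associated gene set; sets are
   compared by Jaccard similarity J(Sᵢ,Sⱼ) = |Sᵢ∩Sⱼ|/|Sᵢ∪Sⱼ|, summarized per
   sample by a rank-sum enrichment score, and ES subgroups (low /
   intermediate / high) are compared by the log-rank test.

## Worked example

```r
library(radrcc)
cfg <- list(seed = 7, selection = selection_config(n_bootstrap = 300, seed = 42))
res <- run_pipeline(cfg)
print(res)
print(res$stratification)
```

```
Radiomics pipeline result
  cohort: 58 patients, 12 metastasis
  signature: WHOLE_IQR_Hist, INNER_Range_Hist, INNER_SD_Hist, OUTER_P10_Hist, OUTER_IQR_Hist, OUTER_Correlation_GLCM, Under80HURatio
  cutoff 2.8366 (84.5%), HR 6.188, log-rank p 3.22e-05

Risk stratification at cutoff 2.8366: 49 low / 9 high
  HR = 6.1882 (95% CI 2.3327-16.4156), log-rank p = 3.22e-05
```

The simulated cohort emulates the clinical study design (58 patients, 12
with postoperative metastasis). The stable signature found on synthetic
images contains the semantic necrosis fraction (`Under80HURatio`) together
with dispersion-type texture features: the generator's class contrast (a
larger necrotic core and a noisier rim in metastasizing tumors) moves many
correlated texture features at once, so the selected set is larger than a
clinical four-feature signature and its exact membership varies with the
seed. The high-risk group (9 of 58 patients above the optimal cutoff) has a
6.2-fold hazard of metastasis, log-rank p = 3×10⁻⁵.

Individual stages are exported and composable: `partition_roi()`,
`extract_feature_table()`, `adasyn_balance()`,
`bootstrap_lasso_selection()`, `fit_rrs_model()`, `optimal_cutoff()`,
`km_logrank()`, `validate_rrs()`, `trait_gene_correlation()`,
`jaccard_matrix()`, `enrichment_scores()`, `cluster_and_survival()`.
`inst/scripts/radgen.R` wraps the pipeline for shell use. See
`vignettes/radiomics-risk-pipeline.Rmd` for the methods account.

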