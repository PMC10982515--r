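# ppaRadiomics

Explainable white-matter radiomics classification of Primary Progressive
Aphasia (PPA) in R.

PPA is a neurodegenerative disorder marked by language deficits, with two
main clinical variants — semantic (svPPA) and non-fluent/agrammatic
(nfvPPA). Distinguishing the variants from each other and from healthy
controls (HC) is a genuine clinical problem: it requires integrating
cognitive scores with subtle, spatially specific white-matter changes on
structural MRI. This package implements, as a tested and reusable pipeline,
an explainable machine-learning approach to that problem, for researchers
who want to run, audit, or extend radiomics-based diagnostic models on
parcellated T1-weighted volumes.

## What the pipeline computes

For each subject, 86 IBSI-style radiomic features per white-matter ROI of a
Desikan-Killiany-style parcellation (34 regions × 2 hemispheres = 68 ROIs,
hence 86 × 68 = 5,848 features per subject):

* 16 first-order statistics of the ROI intensity distribution;
* 24 features from Gray Level Co-occurrence Matrices (GLCM), 16 from Gray
  Level Run Length Matrices (GLRLM), 14 from Gray Level Dependence
  Matrices (GLDM) and 16 from Gray Level Size Zone Matrices (GLSZM), all
  built from intensities discretized to integer gray levels (fixed bin
  width 25 by default).

Per binary contrast (HC vs svPPA, HC vs nfvPPA, svPPA vs nfvPPA) and
feature set (clinical-only; clinical + radiomics):

1. stratified 70:30 train/test split (per class, floor rule — a 53/31/25
   cohort trains on 37/21/17 and tests on 16/10/8);
2. iterative Pearson-correlation redundancy filtering on the training
   split: repeatedly find the pair with max |r|, and while max |r| ≥ 0.9
   remove the member with the higher mean |r| against all retained
   features;
3. an XGBoost classifier tuned by randomized search (60 candidates:
   learning rate U[0.01, 0.1], max depth U{3..10}, boosting rounds
   U{50..200}, subsampling U[0.5, 1]) with stratified 5-fold
   cross-validation maximizing AUC-ROC, refit on the full training split;
4. test-set evaluation with sensitivity, specificity, balanced accuracy
   (= (sens + spec)/2), precision, F1 and AUC-ROC;
5. exact tree Shapley (TreeSHAP) attributions in log-odds units, with
   mean-|SHAP| rankings and beeswarm plots.

Because the source imaging data cannot be redistributed, the package ships
a synthetic cohort generator (`generate_cohort()`): block-parcellated
volumes with group-specific Gaussian-random-field texture effects in
configurable ROIs, and clinical scores (age, sex, education, CDR, CDR
language, two verbal fluencies, Boston Naming Test) drawn from the
published group moments. Everything downstream is tested end-to-end on it.

## Worked example

A study-sized synthetic cohort (53 HC, 31 svPPA, 25 nfvPPA) on a reduced
4-ROI layout, with the generator's default planted effects (left entorhinal
white matter altered in svPPA, left caudal middle frontal in nfvPPA); the
whole block runs in well under a minute:

```r
library(ppaRadiomics)

cfg <- cohort_config(regions = c("entorhinal", "caudalmiddlefrontal"),
                     seed = 1)
cohort <- generate_cohort(cfg)         # 109 subjects, 4 ROIs
features <- extract_features(cohort)   # 109 x (2 + 8 clinical + 344 radiomic)

exp <- run_experiment(
  features,
  space = hp_space(n_iterations = 10, cv_folds = 5),  # scaled-down search
  seed = 1
)
tidy(exp)[, c(1, 2, 3, 6, 7, 8, 9, 12)]
#>          contrast        feature_set positive_class n_features sensitivity
#> 1     HC_vs_svPPA           clinical          svPPA          8       1.000
#> 2     HC_vs_svPPA clinical_radiomics          svPPA        157       1.000
#> 3    HC_vs_nfvPPA           clinical         nfvPPA          8       0.875
#> 4    HC_vs_nfvPPA clinical_radiomics         nfvPPA        161       0.875
#> 5 svPPA_vs_nfvPPA           clinical         nfvPPA          8       0.875
#> 6 svPPA_vs_nfvPPA clinical_radiomics         nfvPPA        159       1.000
#>   specificity balanced_accuracy auc_roc
#> 1           1             1.000       1
#> 2           1             1.000       1
#> 3           1             0.938       1
#> 4           1             0.938       1
#> 5           1             0.938       1
#> 6           1             1.000       1
```

Each row is one fitted model: `n_features` is the column count entering the
classifier (the 8 clinical scores alone, or the correlation-filter
survivors of the joint clinical + radiomics table), and the metric columns
are that model's held-out test-set performance. Note the structure of the
result: clinical scores alone already separate patients from controls, and
adding radiomics lifts the hardest contrast — svPPA vs nfvPPA — from
balanced accuracy 0.938 to 1.0 on this synthetic draw. The attributions
behind any fit are one call away:

```r
res <- exp$results[["svPPA_vs_nfvPPA"]][["clinical_radiomics"]]
head(tidy(res$shap), 3)
#>   rank                                           feature mean_abs_shap
#> 1    1                           lh_entorhinal_glcm_Imc1        2.6868
#> 2    2 lh_entorhinal_glrlm_ShortRunHighGrayLevelEmphasis        0.0374
#> 3    3                           lh_entorhinal_glcm_Idmn        0.0365
#>   direction
#> 1         1
#> 2         1
#> 3        -1

autoplot(res$shap, top_k = 15)   # SHAP beeswarm (ggplot)
cohort_stats(cohort$clinical)    # Table-1-style group statistics
```

Left-entorhinal texture features dominate the ranking — the synthetic
analog of the published left-entorhinal finding for the patient-vs-patient
model.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/ppa-radiomics run-all --out results_dir --seed 1
```

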