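---
title: "White-matter radiomics classification of PPA: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{White-matter radiomics classification of PPA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the pipeline

Primary Progressive Aphasia (PPA) is a neurodegenerative disorder with two
main clinical variants — semantic (svPPA) and non-fluent/agrammatic
(nfvPPA) — whose differential diagnosis is hard because it rests on
integrating clinical scores with subtle, spatially specific brain changes.
`ppaRadiomics` implements an explainable machine-learning pipeline that
classifies the three binary group contrasts (HC vs svPPA, HC vs nfvPPA,
svPPA vs nfvPPA) from white-matter texture:

1. **Feature extraction** — 86 IBSI-style radiomic features per
   white-matter ROI of a Desikan-Killiany-style parcellation (34 regions
   per hemisphere, 68 ROIs, 5,848 features per subject): 16 first-order
   statistics plus four texture-matrix families (24 GLCM, 16 GLRLM,
   14 GLDM, 16 GLSZM).
2. **Redundancy elimination** — iterative pairwise Pearson-correlation
   filtering at cutoff 0.9, fitted on the training split only.
3. **Classification** — an XGBoost binary classifier per contrast, tuned by
   60-candidate randomized search over learning rate [0.01, 0.1], depth
   [3, 10], boosting rounds [50, 200] and row subsampling [0.5, 1], scored
   by mean AUC-ROC over stratified 5-fold cross-validation, refit on the
   full 70% training split and evaluated on the held-out 30% with six
   metrics.
4. **Attribution** — exact tree-path-conditional Shapley values (TreeSHAP)
   on the log-odds scale, summarized as mean-|SHAP| rankings and beeswarm
   plots.

Because the source imaging data cannot be redistributed, the package ships
a synthetic cohort generator with the statistical structure the analysis
assumes, so the entire pipeline is exercised end-to-end in tests.

## Feature definitions and numerical conventions

Within each ROI, intensities are discretized before any texture matrix is
built. The default is a fixed bin width of 25 intensity units — a common
radiomics default; the setting used on the original data is not public, so
it is configurable (`bin_width`, `bin_count`)
and recorded in every output's JSON sidecar. Fixed-width binning assigns
`level(x) = floor((x - min)/w) + 1`; fixed-count binning uses `k`
equal-width bins over `[min, max]`. The gray-level axis spans `1..Ng` with
empty intermediate levels retained, which affects the NonUniformity
normalizations.

Texture matrices follow the standard 3D conventions:

* **GLCM** — symmetric co-occurrence counts at distance 1 over the 13
  unique 3D directions; the 24 features are computed per direction and
  averaged. An ROI with no valid pair in any direction (a single voxel)
  falls back to the zero-distance limit, a diagonal matrix of level
  probabilities, with a warning.
* **GLRLM** — run counts per direction (same 13), features averaged.
* **GLDM** — dependence size of a voxel is 1 + the number of 26-neighbors
  (Chebyshev distance 1) whose level differs by at most `alpha = 0`.
* **GLSZM** — zones are 26-connected components of equal level; a single
  matrix, no directions.

First-order statistics use the raw intensities except Entropy and
Uniformity, which use the discretized histogram. Variance, skewness and
kurtosis are population moments (kurtosis is not excess-corrected);
percentiles use the linear-interpolation convention shared by base R
(type 7) and NumPy. Degenerate ROIs never produce NaN: dispersion features
of a single-voxel ROI are 0 by convention (with a warning), entropy of a
single-level ROI is 0 and uniformity 1. Every kernel is verified in the
test suite against brute-force enumeration oracles (pair enumeration, run
scanning, neighbor counting, flood fill) on hundreds of random small ROIs.

The exact 16-feature first-order list and discretization settings used on
the original data are not public; the default list implemented here is the
standard one, it is configurable, and the 86-count invariant
(16 + 24 + 16 + 14 + 16) is enforced regardless.

## The correlation filter

The filter loops: find the feature pair with the highest absolute Pearson
correlation; stop when that maximum is below the cutoff (0.9 by default, so
a pair at exactly 0.9 is still removed); otherwise drop, of the two, the
feature whose mean absolute correlation against all currently retained
features (excluding itself, including its partner) is higher. Ties — equal
maximal pairs, or equal mean correlations — are broken by original column
order (the earlier pair wins; the later column is removed), making the
procedure deterministic. Zero-variance columns are removed first because
their correlation is undefined. By default the clinical columns are
filtered jointly with the radiomics (set `filter_clinical = FALSE` to
restrict the filter to radiomic columns). The filter is always fitted on
the training split and then applied to the test split.

## Classifier and tuning

The positive class is the patient group for the two HC contrasts and
nfvPPA for the patient-vs-patient contrast (configurable); the confusion
matrix uses a 0.5 probability threshold. L1/L2 regularization strengths are
not tuned; they stay at the ensemble defaults (`alpha = 0`, `lambda = 1`)
and are recorded in the fitted model parameters. "Randomized grid search"
is implemented as uniform sampling — continuous parameters on their
interval, integer parameters on their integer range. Trees are grown with
the exact greedy method: its split thresholds are midpoints between
adjacent training values, whereas histogram-based splitting places
thresholds exactly at data values, hugging one class's cluster edge so
that any test subject extending past its class's training extremum is
misrouted with probability roughly 1/(n+1) per subject *regardless of how
separable the classes are*. At these sample sizes (38 training subjects)
that artifact dominates test error, and exact split enumeration is also
computationally trivial here. No feature scaling is applied (tree ensembles
are invariant to monotone transforms); sex is encoded 0/1.

Reported test metrics follow the standard definitions. Note one
inconsistency in the published tables this pipeline does not reproduce:
rows with sensitivity = 1 and precision = 1 are printed alongside
F1 = 0.947/0.933, which is impossible under F1 = 2PR/(P + R) (it would be
1). The package computes the standard F1.

## Shapley attributions

Attributions are exact tree-path-conditional Shapley values computed from
the fitted ensemble, in raw margin (log-odds) units — the scale on which
tree contributions are additive. Local accuracy (`base + sum(phi) =
margin`) is asserted with a tolerance of 1e-6 *relative* to the margin
magnitude: the ensemble evaluates in single precision, so an absolute 1e-6
is unattainable once margins exceed ~8. Attributions are computed on the
training split by default, matching how the models' feature impact is
assessed; any split can be passed explicitly. The path-dependent
(cover-weighted) expectation is used rather than an interventional
background set, since no background data is designated. The test suite
verifies attributions against a brute-force subset-enumeration oracle (the
cover-weighted conditional-expectation value function over all feature
subsets) on small ensembles, checks that features never used in a split
receive exactly zero, and checks the symmetry axiom on a symmetric
ensemble constructed as the union of two mirror-trained boosters — greedy
boosting itself cannot fit a symmetric ensemble on feature-symmetric data
because the tied round-1 gains are broken positionally.

## The synthetic cohort generator

The generator emulates the study's statistical design, not its anatomy:

* **Layout** — one rectangular block per ROI tiled on a 3D grid (texture
  statistics are location-agnostic, and blocks keep extraction exact and
  fast); the default block is 6x6x6 voxels, comfortably above the 27-voxel
  floor that keeps texture matrices non-degenerate.
* **Intensities** — each ROI block is `baseline_mean + noise_sd * field`
  with a unit-variance Gaussian field (defaults 100 and 10). For ROIs named
  in the effect specification for the subject's group, a mean shift is
  added and the field is smoothed to a longer correlation length (a
  Gaussian random field), lowering contrast-type features and lengthening
  runs — a stand-in mechanism: what is known is *that* patients show
  lower radiomic values, not a generative model of *how*. The default
  effects mirror the study's findings: left entorhinal white matter in
  svPPA, left caudal middle frontal in nfvPPA, both with lower intensity
  (mean shift -15) and smoother texture (correlation length x3).
* **Clinical scores** — drawn per group from truncated normal
  distributions at the published group means and SDs, truncated at each
  test's plausible bounds (Boston Naming Test 0-15, CDR >= 0, fluencies
  >= 0, education 0-30, age 18-100). The underlying location is solved so
  the *truncated* mean equals the configured mean; under heavy truncation
  no truncated normal attains both the configured mean and SD (e.g. a
  lower-truncated normal cannot have mean 0.03 with SD 0.12), so the mean
  is matched exactly and the realized SD may fall below the configured
  one. Sex is Bernoulli with the published female proportions.

What the generator does **not** emulate: brain geometry, scanner artifacts,
partial-volume effects, spatial covariance between ROIs, or any
clinical-imaging correlation beyond shared group membership. Passing tests
therefore demonstrate that the pipeline recovers planted structure of the
assumed form — they say nothing about classification accuracy on real
images, and the study's published accuracies are not reproducible from
synthetic data.

## The recovery experiment

`run_recovery()` is the package's parameter-recovery analog of the study's
left-entorhinal finding. Problem sizes were fixed once for desk-scale
runtime: a 4-ROI layout (entorhinal and caudal middle frontal, both
hemispheres — the two regions the study highlights), the study's patient
group sizes (31 svPPA, 25 nfvPPA), a single planted effect (svPPA,
left entorhinal, mean shift -15, correlation length x3), and the full
60-candidate / 5-fold tuning protocol, repeated over 20 seeds. The planted
arm checks that a left-entorhinal feature reaches the top-3 mean-|SHAP|
ranking in at least 90% of seeds and that mean test balanced accuracy is at
least 0.95 (test sets hold 18 subjects, so one misclassification moves a
single seed by ~0.06; the per-seed fraction is reported alongside). The
null arm re-draws the cohort with no imaging effect and identical clinical
distributions in both groups (healthy-control moments for everyone), the
fully exchangeable null, and checks that balanced accuracy centers on 0.5.

## Reproducibility

Every stage is seeded: the cohort from `cohort_config(seed=)`, splits,
fold assignment, candidate sampling and the ensemble's row subsampling from
the stage seeds that `run_experiment()` derives from its master seed. Two
runs with the same master seed produce byte-identical JSON reports; this is
asserted in the tests.

## Known limitations

* The effect mechanism (mean shift + correlation length) is one of many
  that could produce "lower radiomic values in patients"; recovery results
  are conditional on it.
* Texture statistics estimated on 216-voxel blocks are noisy; group
  separation on texture features at these ROI sizes is weaker than on
  first-order features, which is visible in the recovery experiment's
  reliance on a generous effect size.
* Clinical-only models use all 8 clinical variables (age, sex and education
  included), since the published description does not enumerate the
  clinical model's inputs.
* The post-hoc group comparisons use the two-sample Wilcoxon rank-sum test:
  the groups are independent, so a signed-rank test (sometimes named in
  this context) would not be applicable; post-hoc tests run only when the omnibus test is
  significant at 0.05, unadjusted by default with Bonferroni behind a flag.
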