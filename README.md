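# radbench

Simulation benchmark of machine-learning classifiers and feature-selection
(FS) methods for radiomic-style binary prediction.

Radiomic studies extract hundreds of correlated, mostly non-normal
quantitative features from medical images and use them to predict a binary
clinical outcome (e.g. lymph node involvement, `pN` 0/1). Which classifier
and which FS method to trust depends on sample size, class balance and how
strongly the features are associated with the outcome — quantities that are
unknown on real data. `radbench` answers these questions on synthetic
cohorts where the truth is planted by construction.

The package

* simulates feature panels with controlled correlation, skewness and
  kurtosis via the **Fleishman power method** — each feature is
  `Y = a + bZ + cZ² + dZ³` of a standard normal `Z` with coefficients
  solving the moment equations — combined with the **Vale–Maurelli
  intermediate correlation** construction (the cubic
  `ρ_Y = ρ_Z(b_i b_j + 3b_i d_j + 3d_i b_j + 9d_i d_j) + 2ρ_Z² c_i c_j +
  6ρ_Z³ d_i d_j` is inverted per feature pair, and the resulting matrix is
  repaired to the nearest correlation matrix);
* builds a 3 × 2 × 2 factorial of scenarios — cohort size 600/300/100,
  balanced (50 % positives) vs unbalanced (30 %), high vs low signal — with
  exact per-stratum (FBP:IR = 2:1) class counts, nested subsampling and
  stratified 2/3–1/3 train/validation splits, planting the signal as
  additive shifts on three designated control features;
* benchmarks six classifiers (penalized regression, random forest,
  XGBoost, stepwise logistic regression, k-NN, RBF-SVM) crossed with six
  FS settings (none, hierarchical clustering + Wilcoxon, two PCA variable
  clusterings + Wilcoxon, MRMR, ReliefF), with SMOTE rebalancing of
  unbalanced training folds, scoring validation AUC = Mann–Whitney
  `U/(n₁n₀)`, sensitivity and specificity at threshold 0.5, and recovery
  of the planted controls in top-20 importance lists.

## Worked example

```r
library(radbench)

# statistical portrait of the feature panel: 168 features per stratum,
# 32% normal, 8 correlated families, 3 weakly-coupled control features
ref <- build_reference_stats(seed = derive_seed(1, "reference"))
ref
#> reference_stats: 168 features x 2 strata (FBP, IR); controls: F001, F064, F148

# one scenario: 600 samples, balanced outcome, high signal
spec <- scenario_spec(600, "balanced", "high", ref$controls)
cohort <- build_full_scenario(ref, spec, seed = derive_seed(1, "demo"))
cohort <- split_train_validation(cohort, seed = derive_seed(1, "split"))
cohort
#> cohort: 600 samples x 168 features (300 positives; FBP 400 / IR 200); split 400/200

# train a tuned random forest on the training fold, score the validation fold
tr <- cohort$split$train; va <- cohort$split$validation
fit <- tune_and_fit("RF", cohort$features[tr, ], cohort$outcome[tr], seed = 1)
roc_auc(predict_scores(fit, cohort$features[va, ]), cohort$outcome[va])
#> [1] 0.9981
top20_recovery(extract_importance(fit), cohort$controls)
#> [1] 3
```

The AUC close to 1 reflects the high-signal design (three controls shifted
by 2 pooled SDs each); the recovery count 3 says the forest ranked all
three planted features in its top 20.

The full analysis is a sequence of thin driver scripts over the package:

```sh
Rscript analysis/01_reference_structure.R   # reference moments/correlations
Rscript analysis/02_simulate_scenarios.R    # the 12 cohorts + fidelity checks
Rscript analysis/03_benchmark_grid.R        # 5-replicate sweep (420 cells/rep)
Rscript analysis/04_findings.R              # ordering/effect tests on the sweep
```

`analysis/04_findings.R` prints, among other things (5-replicate sweep,
fixed fast hyperparameters, master seed 1):

```
1) classifier ordering: tree-based 0.851 vs KNN/SVM 0.820 (mean AUC)
3) effect of the feature selection step on AUC
   PR/RF/XGBoost:  no-FS 0.901 vs FS 0.852 (p = 0.000618)
   KNN/SVM:        no-FS 0.733 vs FS 0.838 (p = 1.29e-14)
4) planted-feature recovery: PR, RF, XGBoost 5/5 replicates (all 3 controls)
```

i.e. tree-based classifiers dominate distance-based ones, classifiers with
an embedded selection step do not gain from prior FS while k-NN and SVM
do, and the planted features are recovered reliably at high signal.

## Layout

```
R/                  package code: reference structure, Fleishman/Vale–Maurelli
                    simulator, scenario builder, FS methods, SMOTE, classifier
                    harness, metrics, benchmark orchestration
analysis/           numbered driver scripts (the study pipeline)
scripts/acceptance.R  recomputes the headline AUC targets
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette (model, assumptions, design choices)
results/            small output tables from the analysis scripts
```
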