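# vocims

Cross-validated classification of GC-IMS volatile organic compound (VOC)
profiles.

## What this package is for

Gas chromatography coupled to ion mobility spectrometry (GC-IMS) measures
the VOCs in the headspace above a biofluid sample as a two-dimensional
chromatogram: ion current over retention time (GC column, seconds) and
drift time (IMS tube, milliseconds). In clinical biomarker studies — e.g.
discriminating pregnant women who deliver preterm from those who deliver at
term, or detecting chorioamnionitis or urinary tract infection from urine
headspace — each cohort is a few dozen samples against hundreds of
thousands of pixels, and the analysis stands or falls on leakage-free
validation.

`vocims` implements that analysis as a reusable, tested pipeline:

1. **Preprocessing** — crop the information-bearing central window, zero
   everything below a noise threshold calibrated so each sample keeps on
   the order of 10,000 non-zero pixels, flatten with a recoverable
   pixel-to-(retention, drift) map.
2. **Screening** — within each training fold, rank every pixel by a
   two-sided Wilcoxon rank-sum test and keep the 100 smallest p-values.
3. **Classification** — sparse (L1) logistic regression, a linear SVM with
   Platt-type probability calibration, and a Laplace-approximation Gaussian
   process classifier, all fit on training folds only under stratified
   10-fold cross-validation; out-of-fold class probabilities are pooled so
   every sample is classified exactly once. For a two-group comparison with
   scores `p` and labels `y`, the headline statistic is the area under the
   ROC curve via the Mann-Whitney identity,
   `AUC = Pr(p_case > p_control) + 0.5 Pr(tie)`,
   with a 95% DeLong interval, a rank-based class-separation p-value,
   and a Youden-optimal operating point with exact binomial CIs on
   sensitivity/specificity plus PPV/NPV.
4. **Cohort statistics** — baseline-characteristics tables (one-way ANOVA;
   Fisher's exact test for sparse 2x2 tables, else Pearson chi-squared).
5. **Synthetic cohorts** — a generator of GC-IMS-like chromatograms
   (template Gaussian peaks, reactant-ion ridge, baseline drift, truncated
   Gaussian noise) with planted class effects and clinical covariates
   matching the motivating study's marginals, so the entire pipeline is
   testable without any instrument data.

## Worked example

```r
library(vocims)

# a synthetic cohort: 20 term / 20 preterm, 5 discriminative peaks at
# 1.5x amplitude in the preterm class
design <- plant_effect(
  cohort_design(c(term = 20, preterm = 20), seed = 7),
  n_peaks = 5, multiplier = 1.5
)
cohort <- generate_cohort(design)

# preprocess: shared crop + threshold calibrated to ~10,000 pixels/sample
fm <- build_matrix(cohort$grids, default_crop_window())
fm
#> <feature_matrix> 40 samples x 212000 pixels; threshold 2.7; median nnz/sample 9876

# leakage-free 10-fold CV, Wilcoxon top-100 per fold, three classifiers
cv <- run_cv(fm$matrix, cohort$records$delivery_class, k = 100, seed = 7)
reports <- lapply(colnames(cv$probabilities), function(nm)
  evaluate_probs(cv$probabilities[, nm], cv$labels01, classifier = nm))
select_best_classifier(reports)
#> <eval_report> sparse_logistic_regression: AUC 1.00 (1.00-1.00), p = 6.8e-08,
#>   sens 1.00, spec 1.00, PPV 1.00, NPV 1.00
```

The planted effect is deliberately strong relative to the pixel noise, so
the recovered AUC is near 1; the point of the example is the protocol. On
cohorts with *no* planted effect the same pipeline is calibrated: pooled
out-of-fold AUC averages 0.5, and selecting features once on the full data
before cross-validation (the classic leakage mistake, available via
`run_cv(..., feature_indices = )` for demonstration) inflates it — the
acceptance suite quantifies both.

An end-to-end study — baseline table plus a configurable list of group
contrasts (preterm vs term, WHO gestational-age subgroups, infection flags,
CRP and cervical-length cuts) — runs via `run_study()` or the CLI:

```sh
Rscript exec/vocims simulate --out ws --seed 4
Rscript exec/vocims run --manifest ws/manifest.csv --dir ws --out ws/bundle --seed 4
Rscript exec/vocims report --bundle ws/bundle
```

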