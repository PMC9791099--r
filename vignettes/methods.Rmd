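---
title: "Methods: cross-validated classification of GC-IMS VOC profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-validated classification of GC-IMS VOC profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocims)
```

## The problem

Gas chromatography coupled to ion mobility spectrometry (GC-IMS) measures the
volatile organic compounds (VOCs) in the headspace above a biofluid sample.
Each run yields a two-dimensional chromatogram: ion current as a function of
retention time through the GC column (seconds) and drift time through the IMS
tube (milliseconds). Clinical questions of the form "do urinary VOC profiles
differ between women who deliver preterm and those who deliver at term?" —
or between patients with and without chorioamnionitis or a urinary tract
infection — become high-dimensional two-group classification problems on
these intensity maps, with cohort sizes of a few dozen against hundreds of
thousands of pixels.

`vocims` implements the full analysis path for this setting: preprocessing by
cropping and noise thresholding, within-fold Wilcoxon rank-sum feature
screening, three probabilistic classifiers under 10-fold cross-validation,
ROC-derived discrimination statistics, and baseline-characteristics
comparisons. Because no patient chromatograms are publicly available for this
kind of study, the package also ships a synthetic cohort generator with known
ground truth, so that every stage — and in particular the leakage-freedom of
the cross-validation — is testable end to end.

## The pipeline

### Preprocessing

A raw grid holds mostly noise. Dimensionality is reduced in two fixed steps
applied identically to every sample of a cohort:

1. **Crop** the central window of the retention-time x drift-time plane where
   analyte signal lives (closed coordinate intervals on both axes).
2. **Threshold**: every intensity *strictly below* a cut `tau` is set to
   zero. "Below the threshold" is read literally: values equal to `tau`
   survive. `tau` is placed just above the instrument noise floor; with the
   default calibration it is the smallest candidate on a fixed grid
   (0 to 10 in steps of 0.05) whose median per-sample non-zero count falls
   to 10,000 or fewer pixels, mirroring the target dimensionality of
   around 10,000 non-zero data points per sample.

The cropped, thresholded grid is flattened row-major (retention time outer,
drift time inner) into one row of a samples x pixels feature matrix. Zeros
are observed values, not missingness; the downstream rank test treats them as
measurements below the noise floor. Pixel coordinates are recoverable from
the stored feature index, so any selected feature maps back to a
(retention time, drift time) location. No baseline correction, peak
alignment, reactant-ion-peak normalization or deconvolution is applied.

### Feature screening

Within each training set, every pixel is scored by a two-sided Wilcoxon
rank-sum (Mann-Whitney) test between the two groups, and the `k = 100`
features with the smallest p-values are kept. The p-value is exact — by
enumeration of the U distribution — for combined sample sizes up to 12
without ties, and otherwise uses the normal approximation with midranks, tie
correction and continuity correction. Zero-variance pixels get p = 1 by
definition: they carry no discriminative signal and must rank last. Ties in
the ranking break by ascending pixel index, so selection is reproducible.

### Classifiers

Three probabilistic classifiers are fit to the selected, standardized
features. The study names the families but not the hyperparameters; the
defaults below are fixed once and never tuned per comparison (no inner
cross-validation is performed):

* **Sparse logistic regression** — L1-penalized logistic regression (glmnet)
  at a fixed penalty `lambda = 0.05`. On standardized features and ~36
  training samples this keeps a handful of pixels per fold.
* **Support vector machine** — linear, squared-hinge primal with cost
  `C = 1`, solved by BFGS; decision values are mapped to probabilities by a
  Platt-type sigmoid fit on the training decision values with smoothed
  targets (which keeps the calibration finite under perfect separation).
* **Gaussian process** — binary GP classifier with an RBF kernel, logistic
  link and Laplace approximation; the length-scale is the median pairwise
  training distance (the standard median heuristic), signal variance 1,
  jitter 1e-6. Predictive probabilities use the probit approximation to the
  logistic integral.

Features are standardized to zero mean and unit variance using
*training-fold* statistics only; constant features get unit scale.

### Cross-validation

`run_cv()` makes one pass over 10 folds; each sample is held out exactly
once, and its class probability comes from the model trained without it.
Folds are stratified by class: with subgroup arms as small as 5-17 samples,
unstratified folds frequently produce single-class training sets. Round-robin
dealing of each shuffled class keeps per-fold class counts within one of
proportionality and guarantees both classes in every training set whenever
each class has at least two members — which is also why stratification here
requires only two members per class rather than one per fold (a UTI arm of
n = 7 under 10-fold cross-validation is exactly the situation the original
analysis faced). Everything a fold learns — the Wilcoxon ranking, the
selected pixels, the standardization parameters, the fitted models — derives
from its training rows only; a test-row corruption sentinel in the test suite
asserts this.

The phrase "repeated until every sample has been classified" is implemented
as one pass over the ten folds, not ten independent repetitions: a single
pass already classifies every sample exactly once.

### Evaluation

From the pooled out-of-fold probabilities, `evaluate_probs()` computes:

* **AUC** via the Mann-Whitney identity (half credit for ties), with a 95%
  DeLong-variance normal interval clipped to [0, 1];
* a **class-separation p-value**: the two-sided Mann-Whitney test comparing
  the pooled probabilities between classes. The study does not state its
  p-value construction; a rank test on the same statistic that defines the
  AUC is threshold-free and internally consistent;
* an **operating point** maximizing Youden's J over the observed probability
  cuts (ties resolve toward higher sensitivity), with sensitivity and
  specificity and their exact Clopper-Pearson 95% intervals, and PPV/NPV
  from the confusion counts (empty denominators are reported as missing,
  never as 0).

Per comparison, the best classifier is the one with the highest AUC; ties
break by smaller p-value, then the fixed order SLR, SVM, GP. All values are
kept at full precision internally and rounded to two decimals only at
serialization.

### Baseline characteristics

`baseline_table()` mirrors a clinical Table 1: one-way ANOVA for continuous
variables; for categorical variables Fisher's exact test when the table is
2x2 and any expected cell count is below 5, otherwise Pearson chi-squared
without continuity correction. The original report names both categorical
tests without stating the assignment rule; the expected-count rule used here
is the textbook convention and is asserted to be a pure function of the
table. The two-sided Fisher p sums all hypergeometric tables with the
observed margins whose probability does not exceed the observed table's
(point-probability ordering). Missing values are excluded per variable with
the missing count reported.

## The synthetic cohort generator

`generate_cohort()` emulates the features of the data that matter to the
statistics, not the instrument physics:

* a 120 x 2,500 grid (six-minute GC run, 0-360 s; drift 6-16 ms) whose
  thresholded central crop lands near 10,000 non-zero pixels — the grid
  size is a synthetic convention chosen to match that stated dimensionality,
  since raw vendor grid sizes are not published;
* ~40 shared template peaks, axis-separable Gaussians with log-normal
  amplitudes (median 8 intensity units, i.e. mostly well above the noise);
* a reactant-ion ridge at 7.0 ms, constant across retention time;
* a linear baseline drift (0.002 units/s) and additive Gaussian noise
  (sd 1), with the summed signal clamped at zero — the simplest noise model
  preserving non-negative ion current;
* class effects that are *multiplicative* on peak amplitude (intensity
  scales with analyte concentration), planted by default on the strongest
  template peaks so the effect is expressed above the threshold;
* clinical covariates drawn to reproduce the study's marginal frequencies:
  cohort 26 term / 52 preterm; chorioamnionitis 0/26 term and 28/52
  preterm; UTI 3/26 and 4/52; CRP and cervical length normal with the
  published per-group means and SDs, clamped to plausible ranges;
  gestational-age bands per the WHO categories, with preterm delivery
  before day 259 (37+0 weeks). The preterm split across WHO groups
  (30/17/5) uses the published group-2 and group-3 sizes; the term-side
  split (10/15/1) is not published and is a fixed convention here.

One master seed expands to per-sample seeds through a counter-based scheme,
so regeneration is order-independent and bitwise reproducible; the test
suite hashes entire cohorts across repeated generation.

**What a green test does not establish.** The generator draws independent
samples with homogeneous within-class distributions. Real cohorts have
batch effects, instrument drift across runs, correlated biological
covariates (diet, diuresis, medication), and VOC peaks whose shapes and
positions vary between samples. Recovery of planted effects here
demonstrates that the pipeline is statistically sound and leakage-free, not
that the published effect sizes are reproducible — the patient
chromatograms behind the published AUCs (0.70-0.97) are not deposited, so
those numbers are reference context, not test oracles.

## Numerical and design choices

* Gaussian peak support is truncated at 6 sigma around the snapped center
  (relative error < 2e-8 of the mode); peak centers snap to the nearest
  grid cell so the mode carries exactly the specified amplitude.
* Crop intervals are closed on both ends; thresholding is strict (`< tau`
  zeroed). Both conventions are asserted by tests.
* The exact/approximate switch of the rank-sum test sits at combined n = 12,
  which keeps exactness at the study's smallest subgroup sizes while the
  approximation (used by the compiled column-wise path) covers every
  training set of 13+ samples. The two paths are tested for exact agreement
  on their common domain.
* Fold ids are 1-based (`1..n_folds`), the R convention.
* Per-comparison CV seeds derive from the configuration seed through the
  same counter scheme as the generator, so a report bundle is byte-identical
  across runs with the same configuration — serialization writes no
  timestamps.
* With exactly two groups `anova_p()` reduces to the pooled-variance t-test
  (F = t²), which the suite asserts; a perfectly proportional table gives
  chi-squared p = 1; all p-values live in (0, 1].

## Known limitations

* The crop window and threshold of the original analysis are unpublished;
  they are free configuration here, with defaults tied to the 10,000-pixel
  target.
* Platt calibration on training decision values (rather than on an inner
  validation split) is mildly optimistic about probability scale; it does
  not affect rank-based statistics (AUC, separation p-value).
* Pooled out-of-fold AUC mixes probabilities from ten models; fold-to-fold
  scale differences add variance (though not bias — pooled AUC is mean-0.5
  under label exchangeability, which the acceptance suite verifies by
  simulation).
* **The class-separation p-value is anti-conservative under the null.**
  Pooled out-of-fold probabilities are not independent observations: samples
  in the same fold share a model, and any two fold models share most of
  their training data. The null standard deviation of the pooled AUC is
  therefore larger (about 0.157 at n = 20 + 20 on the default synthetic
  world) than the iid value the rank-sum test assumes (0.091), and the
  nominal 5% test rejects about 26% of null cohorts. The same inflation
  appears with iid Gaussian features in place of chromatograms, so it is a
  property of the protocol — computing a rank test on cross-validated
  scores — rather than of the generator or of any leak. The acceptance
  suite measures this rather than hiding it; practically, it means small
  p-values derived from pooled cross-validated probabilities overstate the
  evidence, and the AUC (whose null mean stays at 0.5) is the more
  trustworthy summary.
* The generator does not model vendor file formats, GC column chemistry,
  ionization physics, or drift-gas dynamics beyond peak shape; chemical
  identification of individual VOCs is out of scope — the pipeline is
  pattern recognition, as in the original analysis.
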