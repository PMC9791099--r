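Package: vocims
Title: Cross-Validated Classification of GC-IMS Volatile Organic Compound Profiles
Version: 0.1.0
Authors@R:
    person("vocims", "maintainers", email = "vocims@example.org", role = c("aut", "cre"))
Description: Tools for discriminating clinical groups from gas chromatography -
    ion mobility spectrometry (GC-IMS) chromatograms of biofluid headspace.
    Provides a synthetic chromatogram cohort generator with planted
    discriminative peaks, crop/threshold/vectorize preprocessing to sparse
    pixel features, leakage-free 10-fold cross-validation with within-fold
    Wilcoxon rank-sum feature screening feeding sparse logistic regression,
    linear support vector machine and Gaussian process classifiers, ROC-based
    evaluation (AUC with DeLong intervals, Youden operating points, predictive
    values), and baseline-characteristics group comparisons (ANOVA,
    chi-squared, Fisher's exact test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
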