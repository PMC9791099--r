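#' Area under the ROC curve
#'
#' Computed through the Mann-Whitney identity: the fraction of
#' (positive, negative) pairs in which the positive scores higher, with half
#' credit for ties — `U / (n0 * n1)`.
#'
#' @param probabilities Numeric scores (higher = more class-1-like).
#' @param labels 0/1 vector (or any two-level vector; the second sorted level
#'   is the positive class).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(probabilities, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop_vocims("vocims_undefined_auc", "AUC requires both classes present")
  }
  r <- rank(probabilities)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

as_binary_labels <- function(labels) {
  if (is.numeric(labels) && all(labels %in% c(0, 1))) {
    return(as.integer(labels))
  }
  labels01(labels)$y01
}

# DeLong variance of the AUC via placement values (midrank form, handles
# ties by half credit).
delong_var <- function(probabilities, y) {
  pos <- probabilities[y == 1]
  neg <- probabilities[y == 0]
  n1 <- length(pos)
  n0 <- length(neg)
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  s10 <- if (n1 > 1) var(v10) else 0
  s01 <- if (n0 > 1) var(v01) else 0
  s10 / n1 + s01 / n0
}

#' DeLong confidence interval for the AUC
#'
#' Normal interval with the DeLong variance estimate, clipped to \[0, 1\].
#' Degenerate inputs (zero variance) collapse to a point interval at the AUC.
#'
#' @inheritParams auc
#' @param level Coverage (default 0.95).
#' @return Numeric vector `c(lower, upper)`; always contains the point AUC.
#' @export
auc_ci <- function(probabilities, labels, level = 0.95) {
  y <- as_binary_labels(labels)
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop_vocims("vocims_undefined_auc", "AUC CI requires >= 2 samples per class")
  }
  a <- auc(probabilities, y)
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(max(delong_var(probabilities, y), 0))
  c(max(0, a - half), min(1, a + half))
}

#' Class-separation p-value
#'
#' Two-sided Mann-Whitney test comparing the pooled out-of-fold probabilities
#' of the two classes (delegates to [ranksum_pvalue()]); rank-based, hence
#' invariant under monotone transforms of the scores.
#'
#' @inheritParams auc
#' @return p-value in (0, 1\].
#' @export
class_separation_pvalue <- function(probabilities, labels) {
  y <- as_binary_labels(labels)
  if (!any(y == 1) || !any(y == 0)) {
    stop_vocims("vocims_undefined_auc", "both classes must be present")
  }
  ranksum_pvalue(probabilities[y == 1], probabilities[y == 0])
}

#' Youden-optimal operating point
#'
#' Scans every observed probability as a cut (predict positive when
#' `probability >= cut`) and returns the one maximizing Youden's
#' J = sensitivity + specificity - 1. Ties resolve toward higher
#' sensitivity (then the lower cut).
#'
#' @inheritParams auc
#' @return List with `threshold`, `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `youden_j`.
#' @export
operating_point <- function(probabilities, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop_vocims("vocims_undefined_auc", "both classes must be present")
  }
  cuts <- sort(unique(probabilities))
  best <- NULL
  for (cut in cuts) {
    pos <- probabilities >= cut
    tp <- sum(pos & y == 1)
    fp <- sum(pos & y == 0)
    sens <- tp / n1
    spec <- 1 - fp / n0
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden_j + 1e-12 ||
        (abs(j - best$youden_j) <= 1e-12 && sens > best$sensitivity + 1e-12)) {
      best <- list(
        threshold = cut, tp = tp, fp = fp, tn = n0 - fp, fn = n1 - tp,
        sensitivity = sens, specificity = spec, youden_j = j
      )
    }
  }
  best
}

#' Predictive values from confusion counts
#'
#' `ppv = tp / (tp + fp)`, `npv = tn / (tn + fn)`; an empty denominator
#' yields `NA` (reported as not available, never silently 0).
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return List with `ppv` and `npv`.
#' @export
predictive_values <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (anyNA(counts) || any(counts < 0)) {
    stop_vocims("vocims_invalid_input", "confusion counts must be non-negative")
  }
  list(
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
  )
}

# Clopper-Pearson exact binomial interval.
clopper_pearson <- function(x, n, level = 0.95) {
  if (n == 0) {
    return(c(NA_real_, NA_real_))
  }
  alpha <- 1 - level
  lower <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower, upper)
}

#' Exact confidence intervals for sensitivity and specificity
#'
#' Clopper-Pearson exact binomial intervals computed from the confusion
#' counts; a zero denominator yields `NA` bounds.
#'
#' @inheritParams predictive_values
#' @param level Coverage (default 0.95).
#' @return List with `sensitivity_ci` and `specificity_ci`, each
#'   `c(lower, upper)`.
#' @export
sens_spec_ci <- function(tp, fp, tn, fn, level = 0.95) {
  counts <- c(tp, fp, tn, fn)
  if (anyNA(counts) || any(counts < 0)) {
    stop_vocims("vocims_invalid_input", "confusion counts must be non-negative")
  }
  list(
    sensitivity_ci = clopper_pearson(tp, tp + fn, level),
    specificity_ci = clopper_pearson(tn, tn + fp, level)
  )
}

#' Evaluate pooled out-of-fold probabilities
#'
#' Assembles one report row in the shape of the study's results tables: AUC
#' with 95% DeLong CI, a rank-based class-separation p-value, the
#' Youden-optimal operating point with sensitivity/specificity and their
#' exact 95% CIs, and PPV/NPV. Values are kept at full precision; rounding
#' happens only at serialization.
#'
#' @inheritParams auc
#' @param classifier Classifier name recorded in the report.
#' @return An object of class `eval_report`.
#' @export
evaluate_probs <- function(probabilities, labels, classifier = "unknown") {
  y <- as_binary_labels(labels)
  op <- operating_point(probabilities, y)
  pv <- predictive_values(op$tp, op$fp, op$tn, op$fn)
  cis <- sens_spec_ci(op$tp, op$fp, op$tn, op$fn)
  structure(
    list(
      classifier = classifier,
      auc = auc(probabilities, y),
      auc_ci_95 = auc_ci(probabilities, y),
      p_value = class_separation_pvalue(probabilities, y),
      threshold = op$threshold,
      sensitivity = op$sensitivity,
      sensitivity_ci_95 = cis$sensitivity_ci,
      specificity = op$specificity,
      specificity_ci_95 = cis$specificity_ci,
      ppv = pv$ppv,
      npv = pv$npv,
      confusion = list(tp = op$tp, fp = op$fp, tn = op$tn, fn = op$fn),
      n_per_class = c(n0 = sum(y == 0), n1 = sum(y == 1))
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s: AUC %.2f (%.2f-%.2f), p = %.3g, sens %.2f, spec %.2f, PPV %.2f, NPV %.2f\n",
    x$classifier, x$auc, x$auc_ci_95[1], x$auc_ci_95[2], x$p_value,
    x$sensitivity, x$specificity, x$ppv, x$npv
  ))
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(
    classifier = x$classifier,
    p_value = x$p_value,
    auc = x$auc,
    auc_lo = x$auc_ci_95[1], auc_hi = x$auc_ci_95[2],
    sensitivity = x$sensitivity,
    sens_lo = x$sensitivity_ci_95[1], sens_hi = x$sensitivity_ci_95[2],
    specificity = x$specificity,
    spec_lo = x$specificity_ci_95[1], spec_hi = x$specificity_ci_95[2],
    ppv = x$ppv, npv = x$npv,
    threshold = x$threshold,
    tp = x$confusion$tp, fp = x$confusion$fp,
    tn = x$confusion$tn, fn = x$confusion$fn,
    n0 = unname(x$n_per_class["n0"]), n1 = unname(x$n_per_class["n1"]),
    stringsAsFactors = FALSE
  )
}

#' Choose the best-performing classifier
#'
#' The study's rule: the classifier with the highest AUC wins; ties break by
#' the smaller class-separation p-value, then by the fixed name order sparse
#' logistic regression, support vector machine, Gaussian process.
#'
#' @param reports Non-empty list of [evaluate_probs()] reports.
#' @return The winning `eval_report`.
#' @export
select_best_classifier <- function(reports) {
  if (length(reports) == 0) {
    stop_vocims("vocims_invalid_input", "at least one report is required")
  }
  name_order <- c(
    "sparse_logistic_regression", "support_vector_machine", "gaussian_process"
  )
  rank_name <- function(nm) {
    i <- match(nm, name_order)
    ifelse(is.na(i), length(name_order) + 1, i)
  }
  aucs <- vapply(reports, `[[`, numeric(1), "auc")
  ps <- vapply(reports, `[[`, numeric(1), "p_value")
  nms <- vapply(reports, `[[`, character(1), "classifier")
  ord <- order(-aucs, ps, rank_name(nms))
  reports[[ord[1]]]
}
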