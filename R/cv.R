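#' Build a cross-validation fold plan
#'
#' Splits `n` samples into `n_folds` near-equal subsets (sizes differ by at
#' most 1). With `stratified = TRUE` (the default) each class is dealt
#' round-robin across folds, so per-fold class counts deviate from
#' proportionality by at most 1 and every training set contains both classes
#' whenever each class has at least 2 members. Deterministic given `seed`.
#'
#' @param labels Sample class labels (any vector with 1 or 2 distinct values;
#'   stratification requires exactly 2 and at least 2 members per class).
#' @param n_folds Number of folds, >= 2 (the pipeline default is 10).
#' @param seed Integer seed governing the shuffle.
#' @param stratified Stratify folds by class (default `TRUE`).
#' @return An object of class `fold_plan`: list with `assignment` (fold id in
#'   `1..n_folds` per sample), `n_folds`, `seed`, `stratified`.
#' @export
make_folds <- function(labels, n_folds = 10, seed = 1, stratified = TRUE) {
  n <- length(labels)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2) {
    stop_vocims("vocims_fold_plan_error", "n_folds must be >= 2")
  }
  if (n < n_folds) {
    stop_vocims(
      "vocims_fold_plan_error",
      sprintf("%d samples cannot fill %d folds", n, n_folds)
    )
  }
  assignment <- integer(n)
  if (stratified) {
    if (length(unique(labels)) != 2) {
      stop_vocims("vocims_fold_plan_error", "stratification requires exactly 2 classes")
    }
    if (min(table(labels)) < 2) {
      stop_vocims(
        "vocims_fold_plan_error",
        "stratification requires >= 2 samples per class (else some training folds lose a class)"
      )
    }
    with_seed(seed, {
      offset <- 0L
      for (cl in sort(unique(as.character(labels)))) {
        idx <- which(as.character(labels) == cl)
        idx <- idx[sample.int(length(idx))]
        assignment[idx] <- ((offset + seq_along(idx) - 1L) %% n_folds) + 1L
        offset <- (offset + length(idx)) %% n_folds
      }
    })
  } else {
    with_seed(seed, {
      idx <- sample.int(n)
      assignment[idx] <- (seq_len(n) - 1L) %% n_folds + 1L
    })
  }
  structure(
    list(
      assignment = assignment, n_folds = as.integer(n_folds),
      seed = as.integer(seed), stratified = stratified
    ),
    class = "fold_plan"
  )
}

# Normalize labels to 0/1: the second of the sorted unique values is class 1.
labels01 <- function(labels) {
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2) {
    stop_vocims(
      "vocims_invalid_labels",
      sprintf("need exactly 2 classes, found %d", length(lev))
    )
  }
  list(y01 = as.integer(as.character(labels) == lev[2]), levels = lev)
}

# Column-wise standardization parameters from training rows only.
train_scaler <- function(Xtr) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}

apply_scaler <- function(X, sc) {
  sweep(sweep(X, 2, sc$mu, "-"), 2, sc$sd, "/")
}

# Shared per-fold core: feature screening, selection, standardization and one
# fit per classifier spec — everything derived from training rows only.
cv_fold_core <- function(X, y01, train, specs, k, feature_indices = NULL) {
  if (length(unique(y01[train])) < 2) {
    stop_vocims("vocims_fold_degenerate", "training portion contains a single class")
  }
  if (is.null(feature_indices)) {
    tr <- which(train)
    pv <- if (length(tr) <= 12) {
      rank_features(X[tr, , drop = FALSE], y01[tr])
    } else {
      # row-subset path in compiled code: no training-matrix copy
      ranksum_cols(X, y01, tr)
    }
    sel <- suppressWarnings(select_top_k(pv, k))
  } else {
    sel <- feature_indices
  }
  Xtr <- X[train, sel, drop = FALSE]
  sc <- train_scaler(Xtr)
  Xtr <- apply_scaler(Xtr, sc)
  Xte <- apply_scaler(X[!train, sel, drop = FALSE], sc)
  probs <- lapply(specs, function(spec) {
    predict_prob(fit_classifier(spec, Xtr, y01[train]), Xte)
  })
  list(selected = sel, probs = probs)
}

#' Fit and predict one fold
#'
#' Runs the within-fold protocol for a single fold and classifier: rank all
#' features by [rank_features()] on the training rows only, keep the `k`
#' smallest p-values, standardize with training statistics, fit the
#' classifier and return class-1 probabilities for the held-out rows. No test
#' row influences screening, scaling or fitting.
#'
#' @param X Feature matrix (samples x features).
#' @param labels Two-class label vector.
#' @param fold_plan A [make_folds()] result.
#' @param fold_id Fold to hold out, in `1..n_folds`.
#' @param spec A [classifier_spec()].
#' @param k Number of features to select (default 100).
#' @return List with `test_idx`, `prob` (class-1 probability per test row)
#'   and `selected` (feature indices used).
#' @export
fit_predict_fold <- function(X, labels, fold_plan, fold_id, spec, k = 100) {
  stopifnot(inherits(fold_plan, "fold_plan"), inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  lab <- labels01(labels)
  train <- fold_plan$assignment != fold_id
  if (!any(!train)) {
    stop_vocims("vocims_fold_plan_error", sprintf("fold %d is empty", fold_id))
  }
  core <- cv_fold_core(X, lab$y01, train, list(spec), k)
  list(
    test_idx = which(!train),
    prob = core$probs[[1]],
    selected = core$selected
  )
}

#' Run leakage-free k-fold cross-validation
#'
#' The central harness: one pass over the folds, each held out exactly once.
#' Within every fold the Wilcoxon screening, top-`k` selection,
#' standardization and classifier fits use training rows only; out-of-fold
#' class probabilities are pooled so that every sample is classified exactly
#' once per classifier. Deterministic given `seed` and configuration.
#'
#' `feature_indices` bypasses within-fold selection with a fixed feature set.
#' Its intended use is demonstrating selection leakage (features chosen on
#' the full data inflate apparent accuracy); it is not part of the honest
#' protocol.
#'
#' @inheritParams fit_predict_fold
#' @param specs List of [classifier_spec()] objects (default: all three).
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed for the fold shuffle.
#' @param stratified Stratify folds by class (default `TRUE`).
#' @param feature_indices Optional fixed feature set (see above).
#' @return An object of class `cv_result`: list with `probabilities` (samples
#'   x classifiers matrix of pooled out-of-fold class-1 probabilities),
#'   `selected` (per-fold list of selected feature indices), `labels01`,
#'   `label_levels`, `fold_plan`, `specs`, `k`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(40 * 30), 40)
#' X[1:20, 3] <- X[1:20, 3] + 3
#' y <- rep(c("a", "b"), each = 20)
#' cv <- run_cv(X, y, n_folds = 5, k = 5, seed = 1)
#' auc(cv$probabilities[, 1], cv$labels01)
#' @export
run_cv <- function(X, labels, specs = default_classifier_specs(),
                   n_folds = 10, k = 100, seed = 1, stratified = TRUE,
                   feature_indices = NULL) {
  X <- as.matrix(X)
  lab <- labels01(labels)
  plan <- make_folds(labels, n_folds = n_folds, seed = seed, stratified = stratified)
  probs <- matrix(
    NA_real_, nrow(X), length(specs),
    dimnames = list(rownames(X), vapply(specs, `[[`, character(1), "name"))
  )
  selected <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    train <- plan$assignment != f
    core <- tryCatch(
      cv_fold_core(X, lab$y01, train, specs, k, feature_indices),
      vocims_fold_degenerate = function(e) {
        stop_vocims(
          "vocims_fold_degenerate",
          sprintf("fold %d: %s", f, conditionMessage(e))
        )
      }
    )
    selected[[f]] <- core$selected
    for (s in seq_along(specs)) {
      probs[!train, s] <- core$probs[[s]]
    }
  }
  structure(
    list(
      probabilities = probs, selected = selected,
      labels01 = lab$y01, label_levels = lab$levels,
      fold_plan = plan, specs = specs, k = k
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(
    sprintf(
      "<cv_result> %d samples (%s), %d folds, k = %d; classifiers: %s\n",
      length(x$labels01),
      paste(sprintf("%s = %d", x$label_levels, table(factor(x$labels01, levels = 0:1))), collapse = ", "),
      x$fold_plan$n_folds, x$k,
      paste(colnames(x$probabilities), collapse = ", ")
    )
  )
  invisible(x)
}
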