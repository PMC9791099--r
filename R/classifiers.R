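#' Classifier specifications
#'
#' The three probabilistic classifiers of the pipeline. Hyperparameters are
#' fixed defaults, never tuned per comparison (no inner cross-validation):
#'
#' * `sparse_logistic_regression` — L1-penalized logistic regression
#'   (glmnet), fixed penalty `lambda` (default 0.05).
#' * `support_vector_machine` — linear squared-hinge SVM (fixed cost `C`,
#'   default 1) with Platt-type sigmoid calibration of the decision values.
#' * `gaussian_process` — binary GP classifier, RBF kernel with the median
#'   pairwise-distance length-scale heuristic, Laplace approximation,
#'   logistic link.
#'
#' @param name One of the three names above.
#' @param ... Hyperparameter overrides (`lambda`, `C`, `lengthscale`).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(name, ...) {
  valid <- c("sparse_logistic_regression", "support_vector_machine", "gaussian_process")
  if (!is.character(name) || length(name) != 1 || !name %in% valid) {
    stop_vocims(
      "vocims_invalid_classifier",
      paste("classifier name must be one of:", paste(valid, collapse = ", "))
    )
  }
  defaults <- switch(name,
    sparse_logistic_regression = list(lambda = 0.05),
    support_vector_machine = list(C = 1),
    gaussian_process = list(lengthscale = NULL) # NULL = median heuristic
  )
  structure(
    list(name = name, hyperparameters = modifyList(defaults, list(...))),
    class = "classifier_spec"
  )
}

#' @rdname classifier_spec
#' @export
default_classifier_specs <- function() {
  list(
    classifier_spec("sparse_logistic_regression"),
    classifier_spec("support_vector_machine"),
    classifier_spec("gaussian_process")
  )
}

# Short display names used in report tables.
classifier_abbrev <- c(
  sparse_logistic_regression = "SLR",
  support_vector_machine = "SVM",
  gaussian_process = "GP"
)

#' Fit a classifier and predict class-1 probabilities
#'
#' Internal-facing but exported for testability. `X` must already be
#' standardized (see [run_cv()], which standardizes with training-fold
#' statistics only).
#'
#' @param spec A [classifier_spec()].
#' @param X Numeric matrix (training rows x selected features).
#' @param y01 Integer vector of 0/1 labels, both classes present.
#' @return A fitted model object of class `voc_classifier`.
#' @export
fit_classifier <- function(spec, X, y01) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  y01 <- as.integer(y01)
  if (length(unique(y01)) != 2 || !all(y01 %in% c(0L, 1L))) {
    stop_vocims("vocims_invalid_labels", "y01 must contain both 0 and 1")
  }
  model <- switch(spec$name,
    sparse_logistic_regression = fit_slr(X, y01, spec$hyperparameters),
    support_vector_machine = fit_svm(X, y01, spec$hyperparameters),
    gaussian_process = fit_gp(X, y01, spec$hyperparameters)
  )
  structure(list(spec = spec, model = model), class = "voc_classifier")
}

#' @rdname fit_classifier
#' @param fit A `voc_classifier`.
#' @export
predict_prob <- function(fit, X) {
  stopifnot(inherits(fit, "voc_classifier"))
  X <- as.matrix(X)
  p <- switch(fit$spec$name,
    sparse_logistic_regression = predict_slr(fit$model, X),
    support_vector_machine = predict_svm(fit$model, X),
    gaussian_process = predict_gp(fit$model, X)
  )
  pmin(1, pmax(0, as.numeric(p)))
}

## --- sparse logistic regression (glmnet backend) ---------------------------

fit_slr <- function(X, y01, hp) {
  pad <- ncol(X) < 2 # glmnet requires >= 2 predictors
  if (pad) {
    X <- cbind(X, 0)
  }
  fit <- withCallingHandlers(
    glmnet::glmnet(
      X, factor(y01, levels = c(0, 1)),
      family = "binomial", alpha = 1,
      lambda = hp$lambda, standardize = FALSE
    ),
    # folds this small are the study's reality; the warning is expected
    warning = function(w) {
      if (grepl("fewer than 8\\s+observations", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  list(fit = fit, lambda = hp$lambda, pad = pad)
}

predict_slr <- function(model, X) {
  if (model$pad) {
    X <- cbind(X, 0)
  }
  as.numeric(predict(model$fit, newx = X, s = model$lambda, type = "response"))
}

## --- linear SVM with Platt calibration -------------------------------------

# Squared-hinge primal: 0.5 ||w||^2 + C sum_i max(0, 1 - y_i (x_i w + b))^2,
# y in {-1, +1}; smooth, solved by BFGS with analytic gradient.
fit_svm <- function(X, y01, hp) {
  y <- ifelse(y01 == 1L, 1, -1)
  n <- nrow(X)
  p <- ncol(X)
  obj <- function(theta) {
    w <- theta[seq_len(p)]
    b <- theta[p + 1]
    margin <- pmax(0, 1 - y * (drop(X %*% w) + b))
    0.5 * sum(w^2) + hp$C * sum(margin^2)
  }
  grad <- function(theta) {
    w <- theta[seq_len(p)]
    b <- theta[p + 1]
    margin <- pmax(0, 1 - y * (drop(X %*% w) + b))
    coefs <- -2 * hp$C * margin * y
    c(w + drop(crossprod(X, coefs)), sum(coefs))
  }
  opt <- optim(rep(0, p + 1), obj, grad, method = "BFGS",
               control = list(maxit = 200, reltol = 1e-10))
  w <- opt$par[seq_len(p)]
  b <- opt$par[p + 1]
  d <- drop(X %*% w) + b
  list(w = w, b = b, platt = platt_fit(d, y01))
}

# Platt's sigmoid p = 1 / (1 + exp(A d + B)) with smoothed targets
# (n1 + 1)/(n1 + 2) and 1/(n0 + 2), which keep the optimum finite even under
# perfect separation of the training decision values.
platt_fit <- function(d, y01) {
  n1 <- sum(y01 == 1L)
  n0 <- sum(y01 == 0L)
  t <- ifelse(y01 == 1L, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  # - sum t log p + (1-t) log(1-p), p = plogis(-(A d + B))
  nll <- function(theta) {
    eta <- theta[1] * d + theta[2]
    p <- stats::plogis(-eta)
    p <- pmin(1 - 1e-12, pmax(1e-12, p))
    -sum(t * log(p) + (1 - t) * log(1 - p))
  }
  opt <- optim(c(-1, 0), nll, method = "BFGS", control = list(maxit = 200, reltol = 1e-10))
  list(A = opt$par[1], B = opt$par[2])
}

predict_svm <- function(model, X) {
  d <- drop(X %*% model$w) + model$b
  stats::plogis(-(model$platt$A * d + model$platt$B))
}

## --- Gaussian process classifier (Laplace approximation) -------------------

rbf_kernel <- function(A, B, lengthscale) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * lengthscale^2))
}

fit_gp <- function(X, y01, hp) {
  n <- nrow(X)
  l <- hp$lengthscale
  if (is.null(l)) {
    dd <- dist(X)
    l <- median(dd)
    if (!is.finite(l) || l <= 0) l <- 1
  }
  K <- rbf_kernel(X, X, l) + diag(1e-6, n)
  # Newton iterations for the Laplace mode (logistic likelihood)
  f <- rep(0, n)
  for (iter in seq_len(100)) {
    p <- stats::plogis(f)
    W <- pmax(p * (1 - p), 1e-12)
    sW <- sqrt(W)
    B <- diag(n) + (sW %o% sW) * K
    L <- chol(B) # B = t(L) %*% L in R's chol convention (upper)
    b <- W * f + (y01 - p)
    Kb <- drop(K %*% b)
    a <- b - sW * backsolve(L, backsolve(L, sW * Kb, transpose = TRUE))
    f_new <- drop(K %*% a)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < 1e-8) break
  }
  p <- stats::plogis(f)
  sW <- sqrt(pmax(p * (1 - p), 1e-12))
  list(
    X = X, lengthscale = l, grad = y01 - p, sW = sW,
    L = chol(diag(n) + (sW %o% sW) * K)
  )
}

predict_gp <- function(model, Xnew) {
  ks <- rbf_kernel(Xnew, model$X, model$lengthscale) # m x n
  fmean <- drop(ks %*% model$grad)
  v <- backsolve(model$L, model$sW * t(ks), transpose = TRUE) # n x m
  fvar <- pmax(1 + 1e-6 - colSums(v^2), 1e-12)
  # MacKay's probit approximation to the logistic predictive integral
  stats::plogis(fmean / sqrt(1 + pi * fvar / 8))
}
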