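test_that("auc matches the Mann-Whitney identity and spec examples", {
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc(c(0.1, 0.4, 0.3, 0.9), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(rep(0.5, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  expect_error(auc(c(0.1, 0.2), c(1, 1)), class = "vocims_undefined_auc")
})

test_that("auc equals brute-force pair counting up to n = 50", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(4:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), sample(c(1, 2, 6), 1)) # ties at low precision
    expect_equal(auc(p, y), pair_auc(p, y), tolerance = 1e-12)
  }
})

test_that("auc complement identity holds for tie-free scores", {
  set.seed(3)
  p <- runif(20)
  y <- rep(c(0, 1), 10)
  expect_equal(auc(p, y) + auc(1 - p, y), 1)
})

test_that("auc_ci is a DeLong interval containing the point estimate", {
  set.seed(9)
  p <- c(rnorm(15, 0.4, 0.15), rnorm(15, 0.6, 0.15))
  y <- rep(c(0, 1), each = 15)
  ci <- auc_ci(p, y)
  a <- auc(p, y)
  expect_true(ci[1] <= a && a <= ci[2])
  expect_true(ci[1] >= 0 && ci[2] <= 1)

  # degenerate all-ties: point interval at 0.5
  ci0 <- auc_ci(rep(0.3, 10), rep(c(0, 1), 5))
  expect_equal(ci0, c(0.5, 0.5))

  # widths shrink with n at fixed effect (Monte-Carlo median over draws)
  width <- function(n, reps = 30) {
    median(vapply(seq_len(reps), function(i) {
      p <- c(rnorm(n / 2, 0.4, 0.15), rnorm(n / 2, 0.6, 0.15))
      y <- rep(c(0, 1), each = n / 2)
      diff(auc_ci(p, y))
    }, numeric(1)))
  }
  set.seed(10)
  expect_lt(width(200), width(20))
})

test_that("class_separation_pvalue is the rank-sum test on probabilities", {
  # perfectly separated 5 vs 5: exact two-sided 2/252
  p <- c(1:5 / 10, 6:10 / 10)
  y <- rep(c(0, 1), each = 5)
  expect_equal(class_separation_pvalue(p, y), 2 / choose(10, 5))
  # monotone-transform invariance
  expect_equal(
    class_separation_pvalue(plogis(p * 7 - 2), y),
    class_separation_pvalue(p, y)
  )
  # identical distributions in both arms: p = 1 (U at its null mean)
  expect_equal(
    class_separation_pvalue(rep(c(0.2, 0.8, 0.4), 2), rep(0:1, each = 3)), 1
  )
})

test_that("operating_point maximizes Youden's J with documented tie-breaks", {
  # perfect separation
  op <- operating_point(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  expect_equal(op$tp + op$fn, 2)
  expect_equal(op$tn + op$fp, 2)

  # all equal: J = 0 everywhere, all-positive call (max sensitivity)
  op0 <- operating_point(rep(0.4, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(op0$youden_j, 0)
  expect_equal(op0$sensitivity, 1)

  # hand-built 6-sample case vs exhaustive search
  p <- c(0.15, 0.35, 0.45, 0.5, 0.7, 0.9)
  y <- c(0, 0, 1, 0, 1, 1)
  op1 <- operating_point(p, y)
  js <- vapply(sort(unique(p)), function(cut) {
    sens <- mean(p[y == 1] >= cut)
    spec <- mean(p[y == 0] < cut)
    sens + spec - 1
  }, numeric(1))
  expect_equal(op1$youden_j, max(js))

  # confusion-count conservation at every cut
  for (cut in sort(unique(p))) {
    pos <- p >= cut
    expect_equal(sum(pos & y == 1) + sum(!pos & y == 1), sum(y == 1))
    expect_equal(sum(!pos & y == 0) + sum(pos & y == 0), sum(y == 0))
  }
})

test_that("predictive values handle empty denominators as NA", {
  expect_equal(predictive_values(2, 0, 3, 0), list(ppv = 1, npv = 1))
  expect_true(is.na(predictive_values(0, 0, 3, 1)$ppv))
  pv <- predictive_values(8, 7, 20, 2)
  expect_equal(pv$ppv, 8 / 15)
  expect_equal(pv$npv, 20 / 22)
})

test_that("sens_spec_ci gives Clopper-Pearson intervals", {
  ci <- sens_spec_ci(10, 0, 10, 0)
  expect_equal(ci$sensitivity_ci[1], 0.025^(1 / 10), tolerance = 1e-10)
  expect_equal(ci$sensitivity_ci, c(0.69, 1), tolerance = 0.01)
  ci0 <- sens_spec_ci(0, 0, 5, 10)
  expect_equal(ci0$sensitivity_ci[1], 0)
  # contains the point estimate
  ci2 <- sens_spec_ci(7, 4, 9, 3)
  expect_true(ci2$sensitivity_ci[1] <= 0.7 && 0.7 <= ci2$sensitivity_ci[2])
})

test_that("evaluate_probs is self-consistent with its confusion counts", {
  set.seed(14)
  p <- c(runif(12, 0, 0.7), runif(12, 0.3, 1))
  y <- rep(c(0, 1), each = 12)
  rep_ <- evaluate_probs(p, y, "gaussian_process")
  cc <- rep_$confusion
  expect_equal(rep_$sensitivity, cc$tp / (cc$tp + cc$fn))
  expect_equal(rep_$specificity, cc$tn / (cc$tn + cc$fp))
  expect_equal(rep_$ppv, cc$tp / (cc$tp + cc$fp))
  expect_equal(rep_$npv, cc$tn / (cc$tn + cc$fn))
  expect_true(rep_$auc_ci_95[1] <= rep_$auc && rep_$auc <= rep_$auc_ci_95[2])
  expect_equal(unname(rep_$n_per_class), c(12, 12))
  df <- as.data.frame(rep_)
  expect_equal(df$auc, rep_$auc)
})

test_that("select_best_classifier applies AUC then p then name order", {
  mk <- function(nm, auc, p) {
    structure(list(classifier = nm, auc = auc, p_value = p), class = "eval_report")
  }
  a <- mk("sparse_logistic_regression", 0.74, 0.3)
  b <- mk("support_vector_machine", 0.56, 0.01)
  expect_identical(select_best_classifier(list(a, b))$classifier, a$classifier)
  expect_identical(select_best_classifier(list(a))$classifier, a$classifier)
  c1 <- mk("gaussian_process", 0.74, 0.01)
  expect_identical(select_best_classifier(list(a, c1))$classifier, "gaussian_process")
  # full tie: fixed name order wins
  d1 <- mk("gaussian_process", 0.7, 0.2)
  d2 <- mk("support_vector_machine", 0.7, 0.2)
  expect_identical(select_best_classifier(list(d1, d2))$classifier, "support_vector_machine")
  expect_error(select_best_classifier(list()), class = "vocims_invalid_input")
})
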