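#' One-way ANOVA p-value
#'
#' Fixed-effects one-way ANOVA computed from sums of squares. With exactly
#' two groups it reduces to the two-sided pooled-variance t-test (F = t^2).
#'
#' @param groups List of >= 2 numeric vectors, each with >= 2 values.
#' @return p-value in (0, 1\], or `NA` when the total variance is zero
#'   (degenerate input).
#' @export
anova_p <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop_vocims("vocims_invalid_input", "groups must be a list of >= 2 numeric vectors")
  }
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop_vocims("vocims_invalid_input", "every group needs >= 2 finite values")
  }
  all_vals <- unlist(groups, use.names = FALSE)
  n <- length(all_vals)
  kk <- length(groups)
  grand <- mean(all_vals)
  if (var(all_vals) == 0) {
    return(NA_real_)
  }
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw == 0) {
    # groups internally constant but different: unbounded evidence
    return(.Machine$double.xmin)
  }
  f_stat <- (ssb / (kk - 1)) / (ssw / (n - kk))
  pf(f_stat, kk - 1, n - kk, lower.tail = FALSE)
}

check_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop_vocims("vocims_invalid_input", "2x2 counts must be non-negative integers")
  }
  counts
}

#' Fisher's exact test (2x2, two-sided)
#'
#' Two-sided exact p by point-probability ordering: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (up to a 1e-7 relative
#' tolerance, the usual guard against floating-point splitting of tied
#' tables).
#'
#' @param a,b,c,d Cell counts: rows = outcome yes/no, columns = group. `a`
#'   and `b` form the first row.
#' @return p-value in (0, 1\], or `NA` when a margin is zero.
#' @examples
#' fisher_exact_p(2, 4, 24, 48) # identical proportions -> 1
#' @export
fisher_exact_p <- function(a, b, c, d) {
  check_2x2(a, b, c, d)
  m <- a + c # column 1 total
  n <- b + d # column 2 total
  k <- a + b # row 1 total
  if (m == 0 || n == 0 || k == 0 || c + d == 0) {
    return(NA_real_)
  }
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Pearson chi-squared test (r x c, no continuity correction)
#'
#' @param tab Matrix of non-negative counts with at least 2 rows and columns.
#' @return p-value in (0, 1\], or `NA` when any expected count is zero.
#' @export
chi_squared_p <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2 || anyNA(tab) || any(tab < 0)) {
    stop_vocims("vocims_invalid_input", "tab must be a >= 2x2 matrix of non-negative counts")
  }
  total <- sum(tab)
  if (total == 0) {
    return(NA_real_)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / total
  if (any(expected == 0)) {
    return(NA_real_)
  }
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  pchisq(stat, df, lower.tail = FALSE)
}

# Expected counts under independence, used by the test-choice rule.
expected_counts <- function(tab) {
  outer(rowSums(tab), colSums(tab)) / sum(tab)
}

#' Baseline characteristics table
#'
#' Group comparisons in the style of a clinical Table 1. Continuous variables
#' are tested by one-way ANOVA; categorical variables by Fisher's exact test
#' when the table is 2x2 and any expected cell count is below 5, otherwise by
#' Pearson chi-squared. Missing values are excluded per variable
#' (complete-case) with the missing count reported.
#'
#' @param manifest Data.frame, one row per sample.
#' @param group_column Name of the grouping column (2+ levels).
#' @param variables Columns to summarize; default: all columns except the
#'   group column, `sample_id`, `class_label` and `chromatogram_path`.
#' @return Data.frame with one row per variable: per-group summary strings
#'   (`mean (sd)` or `yes-count/n`), the test used, its p-value, and the
#'   missing count.
#' @export
baseline_table <- function(manifest, group_column = "delivery_class",
                           variables = NULL) {
  if (!group_column %in% colnames(manifest)) {
    stop_vocims("vocims_schema_error", sprintf("no column '%s' in manifest", group_column))
  }
  grp <- as.factor(manifest[[group_column]])
  if (nlevels(grp) < 2) {
    stop_vocims("vocims_schema_error", "group column must have >= 2 levels")
  }
  if (is.null(variables)) {
    variables <- setdiff(
      colnames(manifest),
      c(group_column, "sample_id", "class_label", "chromatogram_path")
    )
  }
  rows <- lapply(variables, function(v) {
    x <- manifest[[v]]
    ok <- !is.na(x) & !is.na(grp)
    n_missing <- sum(!ok)
    xg <- split(x[ok], droplevels(grp[ok]))
    if (is.numeric(x)) {
      p <- tryCatch(anova_p(xg), vocims_error = function(e) NA_real_)
      summaries <- vapply(
        levels(grp),
        function(l) {
          if (!l %in% names(xg)) return(NA_character_)
          sprintf("%.2f (%.2f)", mean(xg[[l]]), sd(xg[[l]]))
        },
        character(1)
      )
      test <- "anova"
    } else {
      xf <- as.factor(x[ok])
      tab <- table(xf, droplevels(grp[ok]))
      if (nrow(tab) < 2 || ncol(tab) < 2) {
        p <- NA_real_
        test <- "none"
      } else if (nrow(tab) == 2 && ncol(tab) == 2 && any(expected_counts(tab) < 5)) {
        p <- fisher_exact_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
        test <- "fisher"
      } else {
        p <- chi_squared_p(tab)
        test <- "chi_squared"
      }
      summaries <- vapply(
        levels(grp),
        function(l) {
          if (!l %in% colnames(tab)) return(NA_character_)
          if (is.logical(x)) {
            yes <- if ("TRUE" %in% rownames(tab)) tab["TRUE", l] else 0L
            sprintf("%d/%d", yes, sum(tab[, l]))
          } else {
            paste(sprintf("%s:%d", rownames(tab), tab[, l]), collapse = " ")
          }
        },
        character(1)
      )
    }
    out <- data.frame(
      variable = v, test = test, p_value = p, n_missing = n_missing,
      stringsAsFactors = FALSE
    )
    for (i in seq_along(levels(grp))) {
      out[[paste0("group_", levels(grp)[i])]] <- summaries[i]
    }
    out
  })
  res <- do.call(rbind, rows)
  attr(res, "group_sizes") <- table(grp)
  res
}
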