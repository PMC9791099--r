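# Exact null distribution of the Mann-Whitney U statistic for tie-free data:
# counts of rank subsets of size m (from m + n ranks) attaining each U in
# 0..m*n, by the classical two-term recurrence
#   N(u; m, n) = N(u - n; m - 1, n) + N(u; m, n - 1).
exact_u_counts <- function(m, n) {
  prev <- rep(list(1), n + 1) # f(0, j): all mass at u = 0
  for (i in seq_len(m)) {
    cur <- vector("list", n + 1)
    cur[[1]] <- 1 # f(i, 0)
    for (j in seq_len(n)) {
      len <- i * j + 1
      a <- prev[[j + 1]] # f(i - 1, j), shifted by j
      b <- cur[[j]]      # f(i, j - 1)
      av <- c(rep(0, j), a, rep(0, len - j - length(a)))
      bv <- c(b, rep(0, len - length(b)))
      cur[[j + 1]] <- av + bv
    }
    prev <- cur
  }
  prev[[n + 1]]
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' The screening statistic of the pipeline: a two-sided Mann-Whitney test of
#' group A against group B. For combined sample sizes up to 12 without ties
#' the p-value is exact — the probability, over all equally likely rank
#' assignments, of a U statistic at least as far from its null mean as
#' observed. Otherwise a normal approximation with midranks, tie correction
#' and continuity correction is used. Zero-variance input (all values tied)
#' is defined as p = 1: such a feature carries no discriminative signal and
#' must rank last.
#'
#' @param x,y Numeric vectors, each non-empty, all values finite.
#' @param exact_max_n Largest combined size for the exact branch (default 12).
#' @return A p-value in (0, 1].
#' @examples
#' ranksum_pvalue(c(1, 2, 3), c(4, 5, 6)) # 0.1 by exact enumeration
#' @export
ranksum_pvalue <- function(x, y, exact_max_n = 12) {
  if (length(x) == 0 || length(y) == 0) {
    stop_vocims("vocims_invalid_input", "both groups must be non-empty")
  }
  if (!is.numeric(x) || !is.numeric(y) || !all(is.finite(c(x, y)))) {
    stop_vocims("vocims_invalid_input", "group values must be finite numerics")
  }
  m <- length(x)
  n <- length(y)
  comb <- c(x, y)
  if (max(comb) == min(comb)) {
    return(1.0)
  }
  ties <- anyDuplicated(comb) > 0
  r <- rank(comb)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  if (m + n <= exact_max_n && !ties) {
    counts <- exact_u_counts(m, n)
    dev <- abs(seq(0, m * n) - mu)
    p <- sum(counts[dev >= abs(U - mu) - 1e-9]) / choose(m + n, m)
    return(p)
  }
  N <- m + n
  tiesum <- sum(vapply(split(r, r), function(g) length(g)^3 - length(g), numeric(1)))
  sigma2 <- (m * n / 12) * ((N + 1) - tiesum / (N * (N - 1)))
  if (sigma2 <= 0) {
    return(1.0)
  }
  z <- max(abs(U - mu) - 0.5, 0) / sqrt(sigma2)
  min(1, 2 * pnorm(-z))
}

#' Rank every feature by a rank-sum test
#'
#' Applies [ranksum_pvalue()] column-wise: each feature is tested for a
#' location difference between the two label groups. For more than 12 samples
#' the computation runs in compiled code (identical to the scalar
#' approximation branch); otherwise the scalar function (with its exact
#' branch) is applied per column.
#'
#' @param X Numeric matrix, samples in rows, features in columns.
#' @param labels Vector with exactly two distinct values; at least one sample
#'   per group.
#' @return Numeric vector of per-feature p-values in (0, 1].
#' @export
rank_features <- function(X, labels) {
  X <- as.matrix(X)
  if (nrow(X) != length(labels)) {
    stop_vocims("vocims_invalid_input", "labels length must match the number of rows")
  }
  lev <- unique(labels)
  if (length(lev) != 2) {
    stop_vocims(
      "vocims_invalid_labels",
      sprintf("labels must contain exactly 2 classes (found %d)", length(lev))
    )
  }
  grp <- as.integer(labels == lev[1])
  if (nrow(X) <= 12) {
    apply(X, 2, function(col) ranksum_pvalue(col[grp == 1], col[grp == 0]))
  } else {
    ranksum_cols(X, grp, seq_len(nrow(X)))
  }
}

#' Select the k smallest p-values
#'
#' Returns the indices of the `k` features with the smallest p-values, in
#' increasing p-value order; ties break by ascending feature index. If fewer
#' than `k` features exist, all are returned. A warning is raised when fewer
#' than `k` features are non-degenerate (p < 1), since the selection is then
#' padded with uninformative features.
#'
#' @param pvalues Numeric vector of p-values.
#' @param k Number of features to keep, >= 1 (the pipeline default is 100).
#' @return Integer vector of selected feature indices,
#'   length `min(k, length(pvalues))`.
#' @export
select_top_k <- function(pvalues, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    stop_vocims("vocims_invalid_input", "k must be a single integer >= 1")
  }
  k_eff <- min(as.integer(k), length(pvalues))
  sel <- order(pvalues, seq_along(pvalues))[seq_len(k_eff)]
  if (sum(pvalues < 1) < k_eff) {
    warn_vocims(
      "vocims_degenerate_selection",
      sprintf(
        "only %d of %d requested features are non-degenerate (p < 1)",
        sum(pvalues < 1), k_eff
      )
    )
  }
  sel
}
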