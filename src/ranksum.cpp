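#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Column-wise two-sided Wilcoxon rank-sum p-values, normal approximation with
// midranks, tie correction and continuity correction; agrees exactly with the
// scalar R implementation's approximate branch (tested). `grp` flags group-A
// membership per row of X; `rows` (1-based) selects the rows to use, so
// cross-validation folds need no matrix copy. Columns with all selected
// values tied (zero variance) get p = 1.
// [[Rcpp::export]]
NumericVector ranksum_cols(NumericMatrix X, IntegerVector grp, IntegerVector rows) {
  const int n = rows.size(), F = X.ncol(), N = X.nrow();
  int m = 0;
  for (int i = 0; i < n; i++) {
    if (rows[i] < 1 || rows[i] > N) stop("row index out of range");
    m += grp[rows[i] - 1];
  }
  const int nb = n - m;
  if (m == 0 || nb == 0) stop("both groups must be non-empty");
  NumericVector out(F);
  std::vector<std::pair<double, int> > v(n);
  const double mu = (double)m * nb / 2.0;
  const double* xp = REAL(X);
  for (int j = 0; j < F; j++) {
    const double* col = xp + (size_t)j * N;
    // degenerate fast path: all selected values equal (typically all zero)
    const double first = col[rows[0] - 1];
    bool constant = true;
    for (int i = 1; i < n; i++) {
      if (col[rows[i] - 1] != first) { constant = false; break; }
    }
    if (constant) { out[j] = 1.0; continue; }
    for (int i = 0; i < n; i++) {
      const int r = rows[i] - 1;
      v[i] = std::make_pair(col[r], grp[r]);
    }
    std::sort(v.begin(), v.end());
    double tiesum = 0.0, W = 0.0;
    int i = 0;
    while (i < n) {
      int k = i;
      while (k + 1 < n && v[k + 1].first == v[i].first) k++;
      const double avg = (i + k + 2) / 2.0; // 1-based average rank
      const int t = k - i + 1;
      if (t > 1) tiesum += (double)t * t * t - t;
      for (int q = i; q <= k; q++) {
        if (v[q].second) W += avg;
      }
      i = k + 1;
    }
    const double U = W - (double)m * (m + 1) / 2.0;
    const double sigma2 =
      ((double)m * nb / 12.0) * ((n + 1) - tiesum / ((double)n * (n - 1)));
    if (sigma2 <= 0) { out[j] = 1.0; continue; }
    double z = std::fabs(U - mu) - 0.5;
    if (z < 0) z = 0;
    z /= std::sqrt(sigma2);
    double p = 2.0 * R::pnorm(-z, 0.0, 1.0, 1, 0);
    out[j] = p > 1.0 ? 1.0 : p;
  }
  return out;
}
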