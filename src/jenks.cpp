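#include <Rcpp.h>
using namespace Rcpp;

// Fisher-Jenks natural breaks: optimal partition of sorted values into k
// contiguous classes minimizing the within-class sum of squared deviations.
// Standard O(k n^2) dynamic program on prefix sums.
//
// [[Rcpp::export]]
IntegerVector jenks_dp(NumericVector sorted_values, int k) {
  int n = sorted_values.size();
  if (k < 1 || k > n) stop("k must be between 1 and n");
  std::vector<double> s(n + 1, 0.0), s2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    s[i + 1] = s[i] + sorted_values[i];
    s2[i + 1] = s2[i] + sorted_values[i] * sorted_values[i];
  }
  // cost of class covering [i, j] (1-based inclusive)
  auto cost = [&](int i, int j) {
    double sum = s[j] - s[i - 1];
    double sq = s2[j] - s2[i - 1];
    int m = j - i + 1;
    return sq - sum * sum / m;
  };
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<std::vector<double>> dp(k + 1, std::vector<double>(n + 1, INF));
  std::vector<std::vector<int>> arg(k + 1, std::vector<int>(n + 1, 0));
  dp[0][0] = 0.0;
  for (int c = 1; c <= k; ++c) {
    for (int j = c; j <= n; ++j) {
      for (int i = c; i <= j; ++i) {
        double v = dp[c - 1][i - 1] + cost(i, j);
        if (v < dp[c][j]) { dp[c][j] = v; arg[c][j] = i; }
      }
    }
  }
  // recover the last index of each class (1-based)
  IntegerVector ends(k);
  int j = n;
  for (int c = k; c >= 1; --c) {
    ends[c - 1] = j;
    j = arg[c][j] - 1;
  }
  return ends;
}
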