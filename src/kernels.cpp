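#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping, symmetric2 step pattern, no global constraint.
// Local cost c(i,j) = |x_i - y_j|; diagonal steps weighted 2c.
// [[Rcpp::export]]
double dtw_cost_cpp(NumericVector x, NumericVector y) {
  const int n = x.size(), m = y.size();
  std::vector<double> prev(m), cur(m);
  for (int j = 0; j < m; ++j) {
    double c = std::fabs(x[0] - y[j]);
    prev[j] = (j == 0) ? c : prev[j - 1] + c;
  }
  for (int i = 1; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = std::fabs(x[i] - y[j]);
      if (j == 0) {
        cur[0] = prev[0] + c;
      } else {
        double best = prev[j] + c;            // insertion
        double left = cur[j - 1] + c;         // deletion
        double diag = prev[j - 1] + 2.0 * c;  // diagonal, double weight
        if (left < best) best = left;
        if (diag < best) best = diag;
        cur[j] = best;
      }
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// Pool-adjacent-violators: weighted least-squares non-decreasing fit.
// [[Rcpp::export]]
NumericVector pava_cpp(NumericVector y, NumericVector w) {
  const int n = y.size();
  std::vector<double> level(n), weight(n);
  std::vector<int> size(n);
  int top = -1;
  for (int i = 0; i < n; ++i) {
    ++top;
    level[top] = y[i];
    weight[top] = w[i];
    size[top] = 1;
    while (top > 0 && level[top - 1] > level[top]) {
      double wsum = weight[top - 1] + weight[top];
      level[top - 1] = (weight[top - 1] * level[top - 1] +
                        weight[top] * level[top]) / wsum;
      weight[top - 1] = wsum;
      size[top - 1] += size[top];
      --top;
    }
  }
  NumericVector out(n);
  int pos = 0;
  for (int b = 0; b <= top; ++b)
    for (int k = 0; k < size[b]; ++k) out[pos++] = level[b];
  return out;
}

// PERMANOVA permutation pseudo-F values.
// D2: n x n squared distances; grp: 0-based group ids; ord: n x P matrix of
// 1-based permutation indices (sample i receives label grp[ord(i,p)-1]).
// [[Rcpp::export]]
NumericVector permanova_F_cpp(NumericMatrix D2, IntegerVector grp,
                              IntegerMatrix ord, int n_groups) {
  const int n = D2.nrow(), P = ord.ncol();
  // total SS is permutation invariant
  double ss_total = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) ss_total += D2(i, j);
  ss_total /= n;

  std::vector<int> ng(n_groups, 0);
  for (int i = 0; i < n; ++i) ng[grp[i]]++;

  NumericVector F(P);
  std::vector<std::vector<int> > members(n_groups);
  for (int g = 0; g < n_groups; ++g) members[g].reserve(n);
  for (int p = 0; p < P; ++p) {
    for (int g = 0; g < n_groups; ++g) members[g].clear();
    for (int i = 0; i < n; ++i) members[grp[ord(i, p) - 1]].push_back(i);
    double ss_within = 0.0;
    for (int g = 0; g < n_groups; ++g) {
      const std::vector<int>& mem = members[g];
      double s = 0.0;
      const int k = mem.size();
      for (int a = 0; a < k; ++a)
        for (int b = a + 1; b < k; ++b) s += D2(mem[a], mem[b]);
      ss_within += s / k;
    }
    double ss_among = ss_total - ss_within;
    F[p] = (ss_among / (n_groups - 1)) / (ss_within / (n - n_groups));
  }
  return F;
}
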