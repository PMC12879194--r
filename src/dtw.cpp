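#include <Rcpp.h>
using namespace Rcpp;

// Unnormalized DTW cost: local cost |a_i - b_j|, unit-weight steps
// {(i-1,j-1), (i-1,j), (i,j-1)}, no window.
// [[Rcpp::export]]
double dtw_cost_cpp(NumericVector a, NumericVector b) {
  int n = a.size(), m = b.size();
  std::vector<double> prev(m), cur(m);
  for (int j = 0; j < m; ++j)
    prev[j] = std::fabs(a[0] - b[j]) + (j ? prev[j - 1] : 0.0);
  for (int i = 1; i < n; ++i) {
    cur[0] = prev[0] + std::fabs(a[i] - b[0]);
    for (int j = 1; j < m; ++j) {
      double best = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
      cur[j] = best + std::fabs(a[i] - b[j]);
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// Null distribution of DTW costs under value-order shuffling.
// perm_a, perm_b: n_perm x length integer matrices of 1-based orderings.
// [[Rcpp::export]]
NumericVector dtw_null_cpp(NumericVector a, NumericVector b,
                           IntegerMatrix perm_a, IntegerMatrix perm_b) {
  int n_perm = perm_a.nrow();
  NumericVector out(n_perm);
  NumericVector pa(a.size()), pb(b.size());
  for (int k = 0; k < n_perm; ++k) {
    for (int i = 0; i < a.size(); ++i) pa[i] = a[perm_a(k, i) - 1];
    for (int j = 0; j < b.size(); ++j) pb[j] = b[perm_b(k, j) - 1];
    out[k] = dtw_cost_cpp(pa, pb);
  }
  return out;
}
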