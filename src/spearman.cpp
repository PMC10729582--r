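#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact two-sided permutation p-value for Spearman's rho on pre-computed
// (average) ranks. With the marginal rank sets fixed, rho is affine in
// S = sum(rx * ry), so |rho_perm| >= |rho_obs| iff |S - c| >= |S_obs - c|
// with c = n * mean(rx) * mean(ry). Enumerates all n! permutations
// (Heap's algorithm); intended for n <= 10.
// [[Rcpp::export]]
double spearman_exact_pval_cpp(NumericVector rx, NumericVector ry) {
  int n = rx.size();
  std::vector<double> a(ry.begin(), ry.end());
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += rx[i]; my += ry[i]; }
  mx /= n; my /= n;
  double c = n * mx * my;
  double s_obs = 0;
  for (int i = 0; i < n; ++i) s_obs += rx[i] * ry[i];
  double t_obs = std::fabs(s_obs - c) - 1e-9;

  long long hits = 0, total = 0;
  std::vector<int> ctr(n, 0);
  auto score = [&]() {
    double s = 0;
    for (int i = 0; i < n; ++i) s += rx[i] * a[i];
    if (std::fabs(s - c) >= t_obs) ++hits;
    ++total;
  };
  score();
  int i = 0;
  while (i < n) {
    if (ctr[i] < i) {
      if (i % 2 == 0) std::swap(a[0], a[i]); else std::swap(a[ctr[i]], a[i]);
      score();
      ++ctr[i];
      i = 0;
    } else {
      ctr[i] = 0;
      ++i;
    }
  }
  return (double)hits / (double)total;
}
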