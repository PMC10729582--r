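#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher 1D squared distance transform on a sampled
// grid with physical spacing w. f holds squared distances (INF where no
// feature yet); the lower envelope of parabolas rooted at (i*w, f[i]).
static void dt1d(std::vector<double>& f, double w) {
  int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[k]] == INF) { v[k] = q; continue; }
    double s;
    while (true) {
      double xq = q * w, xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; }
      else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  if (f[v[0]] == INF) return; // no features anywhere on this line
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * w;
    d[q] = dx * dx + f[v[k]];
  }
  f = d;
}

// Euclidean distance (physical units) from every voxel to the nearest TRUE
// voxel of `mask`, with anisotropic spacing. Inf if the mask is empty.
// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
  int nd = dim.size();
  std::vector<int> dims(dim.begin(), dim.end());
  long long n = 1;
  for (int d = 0; d < nd; ++d) n *= dims[d];
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> f(n);
  for (long long i = 0; i < n; ++i) f[i] = mask[i] ? 0.0 : INF;

  for (int axis = 0; axis < nd; ++axis) {
    int len = dims[axis];
    if (len == 1) continue;
    long long stride = 1;
    for (int d = 0; d < axis; ++d) stride *= dims[d];
    long long block = stride * len;
    std::vector<double> line(len);
    for (long long base = 0; base < n; base += block) {
      for (long long off = 0; off < stride; ++off) {
        long long p0 = base + off;
        for (int i = 0; i < len; ++i) line[i] = f[p0 + (long long)i * stride];
        dt1d(line, spacing[axis]);
        for (int i = 0; i < len; ++i) f[p0 + (long long)i * stride] = line[i];
      }
    }
  }
  NumericVector out(n);
  for (long long i = 0; i < n; ++i) out[i] = std::sqrt(f[i]);
  out.attr("dim") = dim;
  return out;
}
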