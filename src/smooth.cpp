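#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Reflect index into [0, n-1] (mirror boundary, edge not repeated when n > 1).
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n - 2;
  i = ((i % period) + period) % period;
  return (i < n) ? i : period - i;
}

// 1D correlation with a symmetric kernel along one axis of a column-major
// array. dims has length nd; axis is 0-based.
static void conv_axis(std::vector<double>& a, const std::vector<int>& dims,
                      int axis, const std::vector<double>& k) {
  int nd = (int)dims.size();
  int n = dims[axis];
  int r = ((int)k.size() - 1) / 2;
  long long stride = 1;
  for (int d = 0; d < axis; ++d) stride *= dims[d];
  long long outer = 1;
  for (int d = 0; d < nd; ++d) if (d != axis) outer *= dims[d];

  std::vector<double> line(n), out(n);
  // iterate over all lines along `axis`
  long long total = 1;
  for (int d = 0; d < nd; ++d) total *= dims[d];
  long long block = stride * n; // contiguous block containing the axis
  for (long long base = 0; base < total; base += block) {
    for (long long off = 0; off < stride; ++off) {
      long long p0 = base + off;
      for (int i = 0; i < n; ++i) line[i] = a[p0 + (long long)i * stride];
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int j = -r; j <= r; ++j) s += k[j + r] * line[reflect_idx(i + j, n)];
        out[i] = s;
      }
      for (int i = 0; i < n; ++i) a[p0 + (long long)i * stride] = out[i];
    }
  }
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  return k;
}

// [[Rcpp::export]]
NumericVector gauss_smooth_cpp(NumericVector img, IntegerVector dim,
                               NumericVector sigma) {
  int nd = dim.size();
  std::vector<int> dims(dim.begin(), dim.end());
  std::vector<double> a(img.begin(), img.end());
  for (int d = 0; d < nd; ++d) {
    if (sigma[d] > 0 && dims[d] > 1) {
      std::vector<double> k = gauss_kernel(sigma[d]);
      conv_axis(a, dims, d, k);
    }
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Central finite differences along an axis; order 1 -> (f[i+1]-f[i-1])/2,
// order 2 -> f[i+1]-2f[i]+f[i-1]; reflect boundary.
// [[Rcpp::export]]
NumericVector diff_axis_cpp(NumericVector img, IntegerVector dim, int axis,
                            int order) {
  std::vector<int> dims(dim.begin(), dim.end());
  std::vector<double> a(img.begin(), img.end());
  std::vector<double> k;
  if (order == 1) k = {-0.5, 0.0, 0.5};
  else k = {1.0, -2.0, 1.0};
  if (dims[axis] > 1) conv_axis(a, dims, axis, k);
  else std::fill(a.begin(), a.end(), 0.0);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}
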