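#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary array (2D or 3D, column-major).
// connectivity: 1 = face neighbours (4/6), 2 = full neighbourhood (8/26).
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dim,
                           int connectivity) {
  int nd = dim.size();
  int nx = dim[0], ny = dim[1], nz = (nd == 3) ? dim[2] : 1;
  long long n = (long long)nx * ny * nz;
  std::vector<int> lab(n, 0);

  // neighbour offsets
  std::vector<std::array<int,3>> offs;
  int zr = (nz > 1) ? 1 : 0;
  for (int dz = -zr; dz <= zr; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int nonzero = (dx != 0) + (dy != 0) + (dz != 0);
        if (connectivity == 1 && nonzero > 1) continue;
        offs.push_back({dx, dy, dz});
      }

  int next = 0;
  std::vector<long long> stack;
  for (long long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      long long p = stack.back(); stack.pop_back();
      int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((long long)nx * ny));
      for (auto& o : offs) {
        int X = x + o[0], Y = y + o[1], Z = z + o[2];
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        long long q = (long long)Z * nx * ny + (long long)Y * nx + X;
        if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  IntegerVector out(lab.begin(), lab.end());
  out.attr("dim") = dim;
  return out;
}
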