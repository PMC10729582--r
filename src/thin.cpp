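#include <Rcpp.h>
#include <vector>
#include <array>
using namespace Rcpp;

// Topology-preserving curve thinning.
//
// A foreground voxel is "simple" (deletable without changing topology) when
// (Malandain & Bertrand):
//   3D: exactly one 26-connected foreground component in N26*(p), and exactly
//       one 6-connected background component of N18(p) that is 6-adjacent to p;
//   2D: exactly one 8-connected foreground component in N8*(p), and exactly
//       one 4-connected background component of N8(p) that is 4-adjacent to p.
// Border voxels (per direction sub-iteration) that are simple and not curve
// endpoints (>1 foreground neighbour) are deleted sequentially until stable.

namespace {

struct Grid {
  const std::vector<uint8_t>* img;
  int nx, ny, nz;
  inline int at(int x, int y, int z) const {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0;
    return (*img)[(long long)z * nx * ny + (long long)y * nx + x];
  }
};

// count foreground neighbours (full connectivity)
static int n_fg_neighbors(const Grid& g, int x, int y, int z, bool three_d) {
  int cnt = 0, zr = three_d ? 1 : 0;
  for (int dz = -zr; dz <= zr; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        cnt += g.at(x + dx, y + dy, z + dz);
      }
  return cnt;
}

// local flood fill over a fixed set of offsets; returns component count of
// `value` cells restricted to `domain`, counting only components that touch
// a seed offset.
static bool simple2d(const Grid& g, int x, int y, int z) {
  // neighbourhood occupancy, index (dx+1) + 3*(dy+1)
  int nb[9];
  for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx)
      nb[(dx + 1) + 3 * (dy + 1)] = g.at(x + dx, y + dy, z);
  nb[4] = -1; // exclude centre

  // T8: 8-components of foreground in N8*
  int compFG = 0;
  int seen[9] = {0};
  for (int i = 0; i < 9; ++i) {
    if (nb[i] != 1 || seen[i]) continue;
    ++compFG;
    int stack[9], sp = 0;
    stack[sp++] = i; seen[i] = 1;
    while (sp) {
      int c = stack[--sp];
      int cx = c % 3 - 1, cy = c / 3 - 1;
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int X = cx + dx, Y = cy + dy;
          if (X < -1 || X > 1 || Y < -1 || Y > 1) continue;
          int j = (X + 1) + 3 * (Y + 1);
          if (nb[j] == 1 && !seen[j]) { seen[j] = 1; stack[sp++] = j; }
        }
    }
  }
  if (compFG != 1) return false;

  // T4: 4-components of background in N8 that are 4-adjacent to centre
  int compBG = 0;
  int seenb[9] = {0};
  const int four[4] = {1, 3, 5, 7}; // (0,-1),(-1,0),(1,0),(0,1)
  for (int s = 0; s < 4; ++s) {
    int i = four[s];
    if (nb[i] != 0 || seenb[i]) continue;
    ++compBG;
    int stack[9], sp = 0;
    stack[sp++] = i; seenb[i] = 1;
    while (sp) {
      int c = stack[--sp];
      int cx = c % 3 - 1, cy = c / 3 - 1;
      const int d4[4][2] = {{1,0},{-1,0},{0,1},{0,-1}};
      for (auto& d : d4) {
        int X = cx + d[0], Y = cy + d[1];
        if (X < -1 || X > 1 || Y < -1 || Y > 1) continue;
        int j = (X + 1) + 3 * (Y + 1);
        if (j == 4) continue; // centre not part of background set
        if (nb[j] == 0 && !seenb[j]) { seenb[j] = 1; stack[sp++] = j; }
      }
    }
  }
  return compBG == 1;
}

static inline int idx27(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

static bool simple3d(const Grid& g, int x, int y, int z) {
  int nb[27];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx)
        nb[idx27(dx, dy, dz)] = g.at(x + dx, y + dy, z + dz);
  nb[13] = -1;

  // T26: 26-components of foreground in N26*
  int compFG = 0;
  int seen[27] = {0};
  for (int i = 0; i < 27; ++i) {
    if (nb[i] != 1 || seen[i]) continue;
    ++compFG;
    if (compFG > 1) return false;
    int stack[27], sp = 0;
    stack[sp++] = i; seen[i] = 1;
    while (sp) {
      int c = stack[--sp];
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int X = cx + dx, Y = cy + dy, Z = cz + dz;
            if (X < -1 || X > 1 || Y < -1 || Y > 1 || Z < -1 || Z > 1) continue;
            int j = idx27(X, Y, Z);
            if (nb[j] == 1 && !seen[j]) { seen[j] = 1; stack[sp++] = j; }
          }
    }
  }
  if (compFG != 1) return false;

  // T6: 6-components of background within N18 that are 6-adjacent to centre.
  // N18 = offsets with one or two non-zero coordinates.
  int compBG = 0;
  int seenb[27] = {0};
  const int face[6] = {idx27(-1,0,0), idx27(1,0,0), idx27(0,-1,0),
                       idx27(0,1,0),  idx27(0,0,-1), idx27(0,0,1)};
  for (int s = 0; s < 6; ++s) {
    int i = face[s];
    if (nb[i] != 0 || seenb[i]) continue;
    ++compBG;
    if (compBG > 1) return false;
    int stack[27], sp = 0;
    stack[sp++] = i; seenb[i] = 1;
    while (sp) {
      int c = stack[--sp];
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (auto& d : d6) {
        int X = cx + d[0], Y = cy + d[1], Z = cz + d[2];
        if (X < -1 || X > 1 || Y < -1 || Y > 1 || Z < -1 || Z > 1) continue;
        int nz_ = (X != 0) + (Y != 0) + (Z != 0);
        if (nz_ == 0 || nz_ == 3) continue; // stay within N18, skip centre
        int j = idx27(X, Y, Z);
        if (nb[j] == 0 && !seenb[j]) { seenb[j] = 1; stack[sp++] = j; }
      }
    }
  }
  return compBG == 1;
}

} // namespace

// [[Rcpp::export]]
LogicalVector thin_cpp(LogicalVector mask, IntegerVector dim) {
  int nd = dim.size();
  int nx = dim[0], ny = dim[1], nz = (nd == 3) ? dim[2] : 1;
  bool three_d = nz > 1;
  long long n = (long long)nx * ny * nz;
  std::vector<uint8_t> img(n);
  for (long long i = 0; i < n; ++i) img[i] = mask[i] ? 1 : 0;
  Grid g{&img, nx, ny, nz};

  // current foreground voxel list
  std::vector<long long> fg;
  fg.reserve(1024);
  for (long long i = 0; i < n; ++i) if (img[i]) fg.push_back(i);

  const int dirs3[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  const int dirs2[4][3] = {{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  int ndirs = three_d ? 6 : 4;

  bool changed = true;
  std::vector<long long> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < ndirs; ++d) {
      const int* dd = three_d ? dirs3[d] : dirs2[d];
      cand.clear();
      for (long long p : fg) {
        if (!img[p]) continue;
        int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((long long)nx * ny));
        if (g.at(x + dd[0], y + dd[1], z + dd[2]) == 0) cand.push_back(p);
      }
      for (long long p : cand) {
        if (!img[p]) continue;
        int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((long long)nx * ny));
        if (n_fg_neighbors(g, x, y, z, three_d) <= 1) continue; // endpoint/isolated
        bool simple = three_d ? simple3d(g, x, y, z) : simple2d(g, x, y, z);
        if (simple) { img[p] = 0; changed = true; }
      }
    }
    // compact the foreground list
    size_t w = 0;
    for (size_t i = 0; i < fg.size(); ++i) if (img[fg[i]]) fg[w++] = fg[i];
    fg.resize(w);
  }

  LogicalVector out(n);
  for (long long i = 0; i < n; ++i) out[i] = img[i] != 0;
  out.attr("dim") = dim;
  return out;
}
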