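#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
using namespace Rcpp;

// Incremental 3D convex hull; returns the hull volume. Points within `eps`
// of a face plane are treated as interior (coplanar points contribute no
// volume), which keeps the construction robust on gridded coordinates.

namespace {

struct Vec3 {
  double x, y, z;
  Vec3 operator-(const Vec3& o) const { return {x - o.x, y - o.y, z - o.z}; }
  Vec3 cross(const Vec3& o) const {
    return {y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x};
  }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  double norm() const { return std::sqrt(x * x + y * y + z * z); }
};

struct Face { int a, b, c; Vec3 n; double d; bool alive; };

static Face make_face(int a, int b, int c, const std::vector<Vec3>& P,
                      const Vec3& inside) {
  Face f{a, b, c, {0,0,0}, 0.0, true};
  Vec3 n = (P[b] - P[a]).cross(P[c] - P[a]);
  double d = n.dot(P[a]);
  if (n.dot(inside) > d) { std::swap(f.b, f.c); n = {-n.x, -n.y, -n.z}; d = -d; }
  f.n = n; f.d = d;
  return f;
}

} // namespace

// [[Rcpp::export]]
double convhull_volume_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) return 0.0;
  std::vector<Vec3> P(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    scale = std::max({scale, std::fabs(P[i].x), std::fabs(P[i].y), std::fabs(P[i].z)});
  }
  double eps = 1e-9 * std::max(scale, 1.0);

  // initial tetrahedron from extreme points
  int i0 = 0, i1 = -1;
  for (int i = 1; i < n; ++i)
    if (P[i].x < P[i0].x || (P[i].x == P[i0].x && (P[i].y < P[i0].y ||
        (P[i].y == P[i0].y && P[i].z < P[i0].z)))) i0 = i;
  double best = -1;
  for (int i = 0; i < n; ++i) {
    double d = (P[i] - P[i0]).norm();
    if (d > best) { best = d; i1 = i; }
  }
  if (best < eps) return 0.0;
  int i2 = -1; best = -1;
  Vec3 e = P[i1] - P[i0];
  for (int i = 0; i < n; ++i) {
    double d = e.cross(P[i] - P[i0]).norm();
    if (d > best) { best = d; i2 = i; }
  }
  if (best < eps) return 0.0;
  int i3 = -1; best = -1;
  Vec3 nrm = (P[i1] - P[i0]).cross(P[i2] - P[i0]);
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(nrm.dot(P[i] - P[i0]));
    if (d > best) { best = d; i3 = i; }
  }
  if (best < eps) return 0.0; // coplanar point set

  Vec3 inside = {(P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0,
                 (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0,
                 (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0};

  std::vector<Face> faces;
  faces.push_back(make_face(i0, i1, i2, P, inside));
  faces.push_back(make_face(i0, i1, i3, P, inside));
  faces.push_back(make_face(i0, i2, i3, P, inside));
  faces.push_back(make_face(i1, i2, i3, P, inside));

  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    // faces visible from point i
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      double side = faces[f].n.dot(P[i]) - faces[f].d;
      if (side > eps * std::max(1.0, faces[f].n.norm())) vis.push_back((int)f);
    }
    if (vis.empty()) continue;
    // horizon = undirected edges appearing in exactly one visible face
    std::map<std::pair<int,int>, int> ecount;
    for (int f : vis) {
      int vv[3] = {faces[f].a, faces[f].b, faces[f].c};
      for (int k = 0; k < 3; ++k) {
        int u = vv[k], v = vv[(k + 1) % 3];
        if (u > v) std::swap(u, v);
        ecount[{u, v}]++;
      }
    }
    for (int f : vis) faces[f].alive = false;
    for (auto& kv : ecount)
      if (kv.second == 1)
        faces.push_back(make_face(kv.first.first, kv.first.second, i, P, inside));
  }

  double vol = 0.0;
  for (auto& f : faces) {
    if (!f.alive) continue;
    Vec3 a = P[f.a] - inside, b = P[f.b] - inside, c = P[f.c] - inside;
    vol += a.dot(b.cross(c)) / 6.0;
  }
  return std::fabs(vol);
}
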