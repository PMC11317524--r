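#include <Rcpp.h>
#include <queue>
#include <unordered_set>
#include "geometry.h"

using namespace Rcpp;
using nm::Vec3;

// Quadric-error-metric edge collapse (Garland-Heckbert style) with
// manifold-preserving link-condition checks and normal-flip rejection.
// Planar regions carry zero quadric error, so flat geometry collapses first
// and exactly in place - the "adaptive geometry-preserving" behaviour the
// optimizer relies on.

namespace {

struct Quadric {
  // symmetric 4x4: A (3x3 sym), b (3), c
  double a00 = 0, a01 = 0, a02 = 0, a11 = 0, a12 = 0, a22 = 0;
  double b0 = 0, b1 = 0, b2 = 0, c = 0;
  void add_plane(const Vec3 &n, double d, double w) {
    a00 += w * n.x * n.x; a01 += w * n.x * n.y; a02 += w * n.x * n.z;
    a11 += w * n.y * n.y; a12 += w * n.y * n.z; a22 += w * n.z * n.z;
    b0 += w * d * n.x; b1 += w * d * n.y; b2 += w * d * n.z;
    c += w * d * d;
  }
  void operator+=(const Quadric &o) {
    a00 += o.a00; a01 += o.a01; a02 += o.a02;
    a11 += o.a11; a12 += o.a12; a22 += o.a22;
    b0 += o.b0; b1 += o.b1; b2 += o.b2; c += o.c;
  }
  double eval(const Vec3 &x) const {
    return x.x * (a00 * x.x + 2 * a01 * x.y + 2 * a02 * x.z) +
           x.y * (a11 * x.y + 2 * a12 * x.z) + x.z * a22 * x.z +
           2 * (b0 * x.x + b1 * x.y + b2 * x.z) + c;
  }
  // solve A x = -b; false if near-singular
  bool minimizer(Vec3 &x) const {
    double det = a00 * (a11 * a22 - a12 * a12) -
                 a01 * (a01 * a22 - a12 * a02) +
                 a02 * (a01 * a12 - a11 * a02);
    double scale = std::fabs(a00) + std::fabs(a11) + std::fabs(a22);
    if (std::fabs(det) < 1e-10 * scale * scale * scale + 1e-300) return false;
    double inv = 1.0 / det;
    double i00 = (a11 * a22 - a12 * a12) * inv;
    double i01 = (a02 * a12 - a01 * a22) * inv;
    double i02 = (a01 * a12 - a02 * a11) * inv;
    double i11 = (a00 * a22 - a02 * a02) * inv;
    double i12 = (a02 * a01 - a00 * a12) * inv;
    double i22 = (a00 * a11 - a01 * a01) * inv;
    x = Vec3(-(i00 * b0 + i01 * b1 + i02 * b2),
             -(i01 * b0 + i11 * b1 + i12 * b2),
             -(i02 * b0 + i12 * b1 + i22 * b2));
    return true;
  }
};

struct HeapEntry {
  double cost;
  int u, v, ver_u, ver_v;
  Vec3 pos;
  bool operator<(const HeapEntry &o) const { return cost > o.cost; }
};

}  // namespace

// [[Rcpp::export]]
List cpp_decimate(NumericMatrix vertices, IntegerMatrix triangles,
                  int target_faces, double max_error) {
  const int nv = vertices.nrow(), nt = triangles.nrow();
  std::vector<Vec3> pos(nv);
  for (int i = 0; i < nv; ++i)
    pos[i] = Vec3(vertices(i, 0), vertices(i, 1), vertices(i, 2));
  std::vector<std::array<int, 3>> face(nt);
  for (int f = 0; f < nt; ++f)
    face[f] = {triangles(f, 0) - 1, triangles(f, 1) - 1, triangles(f, 2) - 1};
  std::vector<char> face_alive(nt, 1), vert_alive(nv, 1);
  std::vector<std::vector<int>> vfaces(nv);
  for (int f = 0; f < nt; ++f)
    for (int c = 0; c < 3; ++c) vfaces[face[f][c]].push_back(f);

  auto face_normal_area = [&](int f, Vec3 &n, double &area) {
    Vec3 a = pos[face[f][0]], b = pos[face[f][1]], c = pos[face[f][2]];
    Vec3 cr = nm::cross(b - a, c - a);
    double l = nm::norm(cr);
    area = 0.5 * l;
    n = l > 1e-300 ? cr * (1.0 / l) : Vec3(0, 0, 0);
  };

  std::vector<Quadric> Q(nv);
  for (int f = 0; f < nt; ++f) {
    Vec3 n;
    double area;
    face_normal_area(f, n, area);
    if (area <= 0) continue;
    double d = -nm::dot(n, pos[face[f][0]]);
    for (int c = 0; c < 3; ++c) Q[face[f][c]].add_plane(n, d, area);
  }

  std::vector<int> version(nv, 0);
  std::priority_queue<HeapEntry> heap;

  auto neighbors = [&](int u) {
    std::unordered_set<int> nb;
    for (int f : vfaces[u])
      if (face_alive[f])
        for (int c = 0; c < 3; ++c)
          if (face[f][c] != u) nb.insert(face[f][c]);
    return nb;
  };

  auto push_edge = [&](int u, int v) {
    if (u > v) std::swap(u, v);
    Quadric q = Q[u];
    q += Q[v];
    Vec3 x;
    if (!q.minimizer(x)) {
      Vec3 mid = (pos[u] + pos[v]) * 0.5;
      double cu = q.eval(pos[u]), cv = q.eval(pos[v]), cm = q.eval(mid);
      x = pos[u];
      double best = cu;
      if (cv < best) { best = cv; x = pos[v]; }
      if (cm < best) { best = cm; x = mid; }
    }
    heap.push({std::max(0.0, q.eval(x)), u, v, version[u], version[v], x});
  };

  {
    std::unordered_set<uint64_t> seen;
    for (int f = 0; f < nt; ++f)
      for (int c = 0; c < 3; ++c) {
        int a = face[f][c], b = face[f][(c + 1) % 3];
        uint64_t key = (uint64_t)std::min(a, b) * (nv + 1) + std::max(a, b);
        if (seen.insert(key).second) push_edge(a, b);
      }
  }

  int alive_faces = nt;
  while (alive_faces > target_faces && !heap.empty()) {
    HeapEntry e = heap.top();
    heap.pop();
    int u = e.u, v = e.v;
    if (!vert_alive[u] || !vert_alive[v]) continue;
    if (e.ver_u != version[u] || e.ver_v != version[v]) continue;
    if (e.cost > max_error) break;

    // shared faces along the edge
    std::vector<int> shared;
    for (int f : vfaces[u]) {
      if (!face_alive[f]) continue;
      for (int c = 0; c < 3; ++c)
        if (face[f][c] == v) { shared.push_back(f); break; }
    }
    if (shared.empty()) continue;  // stale: no longer adjacent
    // link condition: common neighbors must be exactly the shared-face
    // third vertices
    std::unordered_set<int> nu = neighbors(u), nvv = neighbors(v);
    std::unordered_set<int> third;
    for (int f : shared)
      for (int c = 0; c < 3; ++c)
        if (face[f][c] != u && face[f][c] != v) third.insert(face[f][c]);
    int common = 0;
    for (int w : nu)
      if (nvv.count(w)) ++common;
    if (common != (int)third.size()) continue;

    // reject collapses that flip or degenerate surviving faces
    bool ok = true;
    for (int which = 0; which < 2 && ok; ++which) {
      int src = which == 0 ? u : v;
      for (int f : vfaces[src]) {
        if (!face_alive[f]) continue;
        bool is_shared = false;
        for (int s : shared)
          if (s == f) { is_shared = true; break; }
        if (is_shared) continue;
        Vec3 p[3], pnew[3];
        for (int c = 0; c < 3; ++c) {
          p[c] = pos[face[f][c]];
          pnew[c] = (face[f][c] == src ||
                     (which == 1 && face[f][c] == u)) ? e.pos : p[c];
          if (which == 1 && face[f][c] == u) pnew[c] = e.pos;
        }
        Vec3 n_old = nm::cross(p[1] - p[0], p[2] - p[0]);
        Vec3 n_new = nm::cross(pnew[1] - pnew[0], pnew[2] - pnew[0]);
        if (nm::norm(n_new) < 1e-14 || nm::dot(n_old, n_new) <= 0) {
          ok = false;
          break;
        }
      }
    }
    if (!ok) continue;

    // apply collapse: v merges into u at e.pos
    pos[u] = e.pos;
    Q[u] += Q[v];
    vert_alive[v] = 0;
    for (int f : shared) {
      if (face_alive[f]) {
        face_alive[f] = 0;
        --alive_faces;
      }
    }
    for (int f : vfaces[v]) {
      if (!face_alive[f]) continue;
      for (int c = 0; c < 3; ++c)
        if (face[f][c] == v) face[f][c] = u;
      vfaces[u].push_back(f);
    }
    version[u]++;
    version[v]++;
    for (int w : neighbors(u)) push_edge(u, w);
    if (alive_faces <= 4) break;
  }

  // compact
  std::vector<int> vmap(nv, -1);
  int nvert = 0;
  for (int f = 0; f < nt; ++f)
    if (face_alive[f])
      for (int c = 0; c < 3; ++c)
        if (vmap[face[f][c]] < 0) vmap[face[f][c]] = nvert++;
  NumericMatrix V(nvert, 3);
  for (int i = 0; i < nv; ++i)
    if (vmap[i] >= 0) {
      V(vmap[i], 0) = pos[i].x;
      V(vmap[i], 1) = pos[i].y;
      V(vmap[i], 2) = pos[i].z;
    }
  IntegerMatrix T(alive_faces, 3);
  int fi = 0;
  for (int f = 0; f < nt; ++f)
    if (face_alive[f]) {
      for (int c = 0; c < 3; ++c) T(fi, c) = vmap[face[f][c]] + 1;
      ++fi;
    }
  return List::create(_["vertices"] = V, _["triangles"] = T);
}
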