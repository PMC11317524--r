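#include <Rcpp.h>
#include "geometry.h"

using namespace Rcpp;
using nm::Vec3;

// All triangle pairs with a proper (positive-length or coplanar-overlap)
// intersection, excluding pairs sharing a vertex index. BVH self-traversal;
// tolerance scales with the bounding-box diagonal.
// [[Rcpp::export]]
IntegerMatrix cpp_self_intersections(NumericMatrix vertices,
                                     IntegerMatrix triangles) {
  const int nv = vertices.nrow(), nt = triangles.nrow();
  if (nt == 0) return IntegerMatrix(0, 2);
  std::vector<double> vflat(3 * (size_t)nv);
  for (int i = 0; i < nv; ++i)
    for (int c = 0; c < 3; ++c) vflat[i + (size_t)c * nv] = vertices(i, c);
  std::vector<int> tri0(3 * (size_t)nt);
  for (int f = 0; f < nt; ++f)
    for (int c = 0; c < 3; ++c) tri0[f + (size_t)c * nt] = triangles(f, c) - 1;

  nm::BVH bvh;
  bvh.build(vflat.data(), nv, tri0.data(), nt);
  Vec3 ext = bvh.nodes[0].box.hi - bvh.nodes[0].box.lo;
  const double eps = 1e-9 * std::max(1e-12, nm::norm(ext));

  auto shares_vertex = [&](int f, int g) {
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b)
        if (tri0[f + (size_t)a * nt] == tri0[g + (size_t)b * nt]) return true;
    return false;
  };

  std::vector<std::pair<int, int>> hits;
  auto test_pair = [&](int f, int g) {
    int lo = std::min(f, g), hi = std::max(f, g);
    if (!bvh.tri_box[lo].overlaps(bvh.tri_box[hi], eps)) return;
    if (shares_vertex(lo, hi)) return;
    Vec3 p0, p1, p2, q0, q1, q2;
    bvh.tri(lo, p0, p1, p2);
    bvh.tri(hi, q0, q1, q2);
    if (nm::tri_tri_intersect(p0, p1, p2, q0, q1, q2, eps))
      hits.push_back({lo, hi});
  };

  std::vector<std::pair<int, int>> stack;
  stack.push_back({0, 0});
  while (!stack.empty()) {
    int n1 = stack.back().first, n2 = stack.back().second;
    stack.pop_back();
    const nm::BVH::Node &a = bvh.nodes[n1];
    const nm::BVH::Node &b = bvh.nodes[n2];
    if (n1 == n2) {
      if (a.left < 0) {
        for (int i = a.start; i < a.start + a.count; ++i)
          for (int j = i + 1; j < a.start + a.count; ++j)
            test_pair(bvh.order[i], bvh.order[j]);
      } else {
        stack.push_back({a.left, a.left});
        stack.push_back({a.right, a.right});
        stack.push_back({a.left, a.right});
      }
      continue;
    }
    if (!a.box.overlaps(b.box, eps)) continue;
    if (a.left < 0 && b.left < 0) {
      for (int i = a.start; i < a.start + a.count; ++i)
        for (int j = b.start; j < b.start + b.count; ++j)
          test_pair(bvh.order[i], bvh.order[j]);
    } else if (a.left < 0) {
      stack.push_back({n1, b.left});
      stack.push_back({n1, b.right});
    } else if (b.left < 0) {
      stack.push_back({a.left, n2});
      stack.push_back({a.right, n2});
    } else {
      stack.push_back({a.left, b.left});
      stack.push_back({a.left, b.right});
      stack.push_back({a.right, b.left});
      stack.push_back({a.right, b.right});
    }
  }
  std::sort(hits.begin(), hits.end());
  hits.erase(std::unique(hits.begin(), hits.end()), hits.end());
  IntegerMatrix out((int)hits.size(), 2);
  for (size_t i = 0; i < hits.size(); ++i) {
    out(i, 0) = hits[i].first + 1;
    out(i, 1) = hits[i].second + 1;
  }
  return out;
}
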