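#include <Rcpp.h>
#include <unordered_map>
#include <queue>
#include "geometry.h"

using namespace Rcpp;
using nm::Vec3;

// Consistent winding by propagation over shared edges (per connected
// component), then a whole-component flip wherever the component's signed
// volume comes out negative, so normals point outward.
// [[Rcpp::export]]
IntegerMatrix cpp_orient_triangles(NumericMatrix vertices,
                                   IntegerMatrix triangles) {
  const int nv = vertices.nrow(), nt = triangles.nrow();
  std::vector<std::array<int, 3>> tri(nt);
  for (int f = 0; f < nt; ++f)
    tri[f] = {triangles(f, 0) - 1, triangles(f, 1) - 1, triangles(f, 2) - 1};

  std::unordered_map<uint64_t, std::vector<int>> edge_faces;
  edge_faces.reserve(nt * 2);
  auto ekey = [&](int a, int b) {
    uint64_t lo = (uint64_t)std::min(a, b), hi = (uint64_t)std::max(a, b);
    return lo * (uint64_t)(nv + 1) + hi;
  };
  for (int f = 0; f < nt; ++f)
    for (int c = 0; c < 3; ++c)
      edge_faces[ekey(tri[f][c], tri[f][(c + 1) % 3])].push_back(f);

  // directed edge (a -> b) present in face f?
  auto has_directed = [&](int f, int a, int b) {
    for (int c = 0; c < 3; ++c)
      if (tri[f][c] == a && tri[f][(c + 1) % 3] == b) return true;
    return false;
  };

  std::vector<int> comp(nt, -1);
  int n_comp = 0;
  for (int seed = 0; seed < nt; ++seed) {
    if (comp[seed] >= 0) continue;
    int cid = n_comp++;
    std::queue<int> q;
    comp[seed] = cid;
    q.push(seed);
    std::vector<int> members;
    while (!q.empty()) {
      int f = q.front();
      q.pop();
      members.push_back(f);
      for (int c = 0; c < 3; ++c) {
        int a = tri[f][c], b = tri[f][(c + 1) % 3];
        const std::vector<int> &nb = edge_faces[ekey(a, b)];
        if (nb.size() != 2) continue;  // skip boundary / non-manifold edges
        for (int g : nb) {
          if (g == f || comp[g] >= 0) continue;
          // consistent orientation: g must traverse the edge as b -> a
          if (has_directed(g, a, b))
            std::swap(tri[g][1], tri[g][2]);
          comp[g] = cid;
          q.push(g);
        }
      }
    }
    // outward flip per component
    double vol6 = 0;
    for (int f : members) {
      Vec3 a(vertices(tri[f][0], 0), vertices(tri[f][0], 1),
             vertices(tri[f][0], 2));
      Vec3 b(vertices(tri[f][1], 0), vertices(tri[f][1], 1),
             vertices(tri[f][1], 2));
      Vec3 c(vertices(tri[f][2], 0), vertices(tri[f][2], 1),
             vertices(tri[f][2], 2));
      vol6 += nm::dot(a, nm::cross(b, c));
    }
    if (vol6 < 0)
      for (int f : members) std::swap(tri[f][1], tri[f][2]);
  }

  IntegerMatrix out(nt, 3);
  for (int f = 0; f < nt; ++f)
    for (int c = 0; c < 3; ++c) out(f, c) = tri[f][c] + 1;
  return out;
}
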