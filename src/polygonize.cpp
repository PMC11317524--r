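#include <Rcpp.h>
#include <unordered_map>
#include "geometry.h"

using namespace Rcpp;
using nm::Vec3;

// Polygonization of a binary occupancy lattice by marching tetrahedra on a
// parity-alternating 5-tetrahedra cube decomposition. Grid nodes sit at
// voxel centers with field value +1 (occupied) / -1 (empty); the iso-0 level
// set of the piecewise-linear interpolant is extracted. Because 0 is a
// regular value (no node is 0) and adjacent cubes share face diagonals, the
// output is always a closed, self-intersection-free two-manifold - the
// topology-consistency guarantee the pipeline relies on.

static const int TETS_EVEN[5][4] = {
    {0, 1, 2, 4}, {1, 3, 2, 7}, {1, 5, 4, 7}, {2, 4, 6, 7}, {1, 2, 4, 7}};
// mirrored through x (corner index XOR 1) for odd-parity cubes
static const int TETS_ODD[5][4] = {
    {1, 0, 3, 5}, {0, 2, 3, 6}, {0, 4, 5, 6}, {3, 5, 7, 6}, {0, 3, 5, 6}};

// [[Rcpp::export]]
List cpp_polygonize(LogicalVector occupancy, IntegerVector dims,
                    NumericVector origin, double voxel_size) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double h = voxel_size;
  const Vec3 o(origin[0], origin[1], origin[2]);
  auto lin = [&](int i, int j, int k) {
    return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
  };
  auto node_pos = [&](R_xlen_t id) {
    int i = (int)(id % nx);
    int j = (int)((id / nx) % ny);
    int k = (int)(id / ((R_xlen_t)nx * ny));
    return Vec3(o.x + (i + 0.5) * h, o.y + (j + 0.5) * h, o.z + (k + 0.5) * h);
  };

  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  auto cut_vertex = [&](R_xlen_t a, R_xlen_t b) {
    uint64_t lo = (uint64_t)std::min(a, b), hi = (uint64_t)std::max(a, b);
    uint64_t key = lo * (uint64_t)(nx * (R_xlen_t)ny * nz) + hi;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    Vec3 pa = node_pos(a), pb = node_pos(b);
    Vec3 p = (pa + pb) * 0.5;  // binary field: cut at the midpoint
    vx.push_back(p.x);
    vy.push_back(p.y);
    vz.push_back(p.z);
    int id = (int)vx.size() - 1;
    edge_vertex.emplace(key, id);
    return id;
  };

  auto emit_tri = [&](int a, int b, int c, const Vec3 &inside_ref) {
    // orient so the normal points away from the interior
    Vec3 pa(vx[a], vy[a], vz[a]), pb(vx[b], vy[b], vz[b]),
        pc(vx[c], vy[c], vz[c]);
    Vec3 n = nm::cross(pb - pa, pc - pa);
    Vec3 cen = (pa + pb + pc) * (1.0 / 3.0);
    if (nm::dot(n, inside_ref - cen) > 0) std::swap(b, c);
    tri.push_back(a);
    tri.push_back(b);
    tri.push_back(c);
  };

  R_xlen_t corner_off[8];
  for (int c = 0; c < 8; ++c)
    corner_off[c] = lin(c & 1, (c >> 1) & 1, (c >> 2) & 1);

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        R_xlen_t base = lin(i, j, k);
        int occ_mask = 0;
        for (int c = 0; c < 8; ++c)
          if (occupancy[base + corner_off[c]]) occ_mask |= (1 << c);
        if (occ_mask == 0 || occ_mask == 255) continue;
        const int(*tets)[4] =
            (((i + j + k) & 1) == 0) ? TETS_EVEN : TETS_ODD;
        for (int t = 0; t < 5; ++t) {
          R_xlen_t n_id[4];
          bool pos[4];
          int npos = 0;
          for (int v = 0; v < 4; ++v) {
            n_id[v] = base + corner_off[tets[t][v]];
            pos[v] = (occ_mask >> tets[t][v]) & 1;
            if (pos[v]) ++npos;
          }
          if (npos == 0 || npos == 4) continue;
          // reference point on the interior side: centroid of + nodes
          Vec3 inside_ref(0, 0, 0);
          for (int v = 0; v < 4; ++v)
            if (pos[v]) inside_ref = inside_ref + node_pos(n_id[v]);
          inside_ref = inside_ref * (1.0 / npos);
          if (npos == 1 || npos == 3) {
            bool lone_sign = (npos == 1);
            int lone = 0;
            for (int v = 0; v < 4; ++v)
              if (pos[v] == lone_sign) lone = v;
            int vs[3], m = 0;
            for (int v = 0; v < 4; ++v)
              if (v != lone) vs[m++] = v;
            int a = cut_vertex(n_id[lone], n_id[vs[0]]);
            int b = cut_vertex(n_id[lone], n_id[vs[1]]);
            int c = cut_vertex(n_id[lone], n_id[vs[2]]);
            emit_tri(a, b, c, inside_ref);
          } else {
            int p[2], n[2], mp = 0, mn = 0;
            for (int v = 0; v < 4; ++v)
              (pos[v] ? p[mp++] : n[mn++]) = v;
            int e00 = cut_vertex(n_id[p[0]], n_id[n[0]]);
            int e01 = cut_vertex(n_id[p[0]], n_id[n[1]]);
            int e11 = cut_vertex(n_id[p[1]], n_id[n[1]]);
            int e10 = cut_vertex(n_id[p[1]], n_id[n[0]]);
            // quad cycle e00 -> e01 -> e11 -> e10
            emit_tri(e00, e01, e11, inside_ref);
            emit_tri(e00, e11, e10, inside_ref);
          }
        }
      }

  int nvert = (int)vx.size();
  NumericMatrix V(nvert, 3);
  for (int i = 0; i < nvert; ++i) {
    V(i, 0) = vx[i];
    V(i, 1) = vy[i];
    V(i, 2) = vz[i];
  }
  int ntri = (int)tri.size() / 3;
  IntegerMatrix T(ntri, 3);
  for (int f = 0; f < ntri; ++f)
    for (int c = 0; c < 3; ++c) T(f, c) = tri[3 * f + c] + 1;
  return List::create(_["vertices"] = V, _["triangles"] = T);
}
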