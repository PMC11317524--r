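#ifndef NEUROMESH_GEOMETRY_H
#define NEUROMESH_GEOMETRY_H

#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <cstdint>

namespace nm {

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3 &o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3 &o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double operator[](int i) const { return i == 0 ? x : (i == 1 ? y : z); }
};

inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x);
}
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

struct AABB {
  Vec3 lo, hi;
  AABB() {
    lo = Vec3(1e300, 1e300, 1e300);
    hi = Vec3(-1e300, -1e300, -1e300);
  }
  void expand(const Vec3 &p) {
    lo.x = std::min(lo.x, p.x); lo.y = std::min(lo.y, p.y);
    lo.z = std::min(lo.z, p.z);
    hi.x = std::max(hi.x, p.x); hi.y = std::max(hi.y, p.y);
    hi.z = std::max(hi.z, p.z);
  }
  void expand(const AABB &b) { expand(b.lo); expand(b.hi); }
  bool overlaps(const AABB &b, double eps) const {
    return lo.x <= b.hi.x + eps && hi.x + eps >= b.lo.x &&
           lo.y <= b.hi.y + eps && hi.y + eps >= b.lo.y &&
           lo.z <= b.hi.z + eps && hi.z + eps >= b.lo.z;
  }
};

// ---- triangle-box overlap (separating axis theorem) ------------------------

// Akenine-Moller style SAT test: triangle vs axis-aligned box given box
// center and half sizes.
inline bool tri_box_overlap(const Vec3 &center, const Vec3 &half,
                            const Vec3 &ta, const Vec3 &tb, const Vec3 &tc) {
  Vec3 v0 = ta - center, v1 = tb - center, v2 = tc - center;
  // box axes
  auto minmax3 = [](double a, double b, double c, double &mn, double &mx) {
    mn = std::min(a, std::min(b, c));
    mx = std::max(a, std::max(b, c));
  };
  double mn, mx;
  minmax3(v0.x, v1.x, v2.x, mn, mx);
  if (mn > half.x || mx < -half.x) return false;
  minmax3(v0.y, v1.y, v2.y, mn, mx);
  if (mn > half.y || mx < -half.y) return false;
  minmax3(v0.z, v1.z, v2.z, mn, mx);
  if (mn > half.z || mx < -half.z) return false;
  // triangle plane vs box
  Vec3 e0 = v1 - v0, e1 = v2 - v1, e2 = v0 - v2;
  Vec3 n = cross(e0, e1);
  double d = -dot(n, v0);
  double r = half.x * std::fabs(n.x) + half.y * std::fabs(n.y) +
             half.z * std::fabs(n.z);
  if (std::fabs(d) > r) return false;
  // 9 cross-product axes
  const Vec3 *edges[3] = {&e0, &e1, &e2};
  const Vec3 *verts[3] = {&v0, &v1, &v2};
  for (int i = 0; i < 3; ++i) {
    const Vec3 &e = *edges[i];
    // axis = cross(x, e) = (0, -e.z, e.y)
    {
      double p0 = -e.z * verts[0]->y + e.y * verts[0]->z;
      double p1 = -e.z * verts[1]->y + e.y * verts[1]->z;
      double p2 = -e.z * verts[2]->y + e.y * verts[2]->z;
      minmax3(p0, p1, p2, mn, mx);
      double rad = half.y * std::fabs(e.z) + half.z * std::fabs(e.y);
      if (mn > rad || mx < -rad) return false;
    }
    // axis = cross(y, e) = (e.z, 0, -e.x)
    {
      double p0 = e.z * verts[0]->x - e.x * verts[0]->z;
      double p1 = e.z * verts[1]->x - e.x * verts[1]->z;
      double p2 = e.z * verts[2]->x - e.x * verts[2]->z;
      minmax3(p0, p1, p2, mn, mx);
      double rad = half.x * std::fabs(e.z) + half.z * std::fabs(e.x);
      if (mn > rad || mx < -rad) return false;
    }
    // axis = cross(z, e) = (-e.y, e.x, 0)
    {
      double p0 = -e.y * verts[0]->x + e.x * verts[0]->y;
      double p1 = -e.y * verts[1]->x + e.x * verts[1]->y;
      double p2 = -e.y * verts[2]->x + e.x * verts[2]->y;
      minmax3(p0, p1, p2, mn, mx);
      double rad = half.x * std::fabs(e.y) + half.y * std::fabs(e.x);
      if (mn > rad || mx < -rad) return false;
    }
  }
  return true;
}

// ---- ray-triangle (Moller-Trumbore) ----------------------------------------

// returns t > 0 on hit along dir from orig, -1 otherwise
inline double ray_tri(const Vec3 &orig, const Vec3 &dir, const Vec3 &a,
                      const Vec3 &b, const Vec3 &c) {
  const double EPS = 1e-12;
  Vec3 e1 = b - a, e2 = c - a;
  Vec3 p = cross(dir, e2);
  double det = dot(e1, p);
  if (std::fabs(det) < EPS) return -1.0;
  double inv = 1.0 / det;
  Vec3 t = orig - a;
  double u = dot(t, p) * inv;
  if (u < 0.0 || u > 1.0) return -1.0;
  Vec3 q = cross(t, e1);
  double v = dot(dir, q) * inv;
  if (v < 0.0 || u + v > 1.0) return -1.0;
  double thit = dot(e2, q) * inv;
  return thit > EPS ? thit : -1.0;
}

// ---- triangle-triangle intersection (Moller interval test) -----------------

inline bool coplanar_tri_tri(const Vec3 &n, const Vec3 &v0, const Vec3 &v1,
                             const Vec3 &v2, const Vec3 &u0, const Vec3 &u1,
                             const Vec3 &u2) {
  // project to the dominant plane and run 2D edge tests
  int i0, i1;
  double ax = std::fabs(n.x), ay = std::fabs(n.y), az = std::fabs(n.z);
  if (ax > ay && ax > az) { i0 = 1; i1 = 2; }
  else if (ay > az) { i0 = 0; i1 = 2; }
  else { i0 = 0; i1 = 1; }
  auto edge_edge = [&](const Vec3 &a, const Vec3 &b, const Vec3 &c,
                       const Vec3 &d) {
    double ax1 = b[i0] - a[i0], ay1 = b[i1] - a[i1];
    double bx = c[i0] - d[i0], by = c[i1] - d[i1];
    double cx = a[i0] - c[i0], cy = a[i1] - c[i1];
    double f = ay1 * bx - ax1 * by;
    double dd = by * cx - bx * cy;
    if ((f > 0 && dd >= 0 && dd <= f) || (f < 0 && dd <= 0 && dd >= f)) {
      double e = ax1 * cy - ay1 * cx;
      if (f > 0) { if (e >= 0 && e <= f) return true; }
      else { if (e <= 0 && e >= f) return true; }
    }
    return false;
  };
  const Vec3 *t1[3] = {&v0, &v1, &v2};
  const Vec3 *t2[3] = {&u0, &u1, &u2};
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      if (edge_edge(*t1[i], *t1[(i + 1) % 3], *t2[j], *t2[(j + 1) % 3]))
        return true;
  auto point_in_tri = [&](const Vec3 &p, const Vec3 &a, const Vec3 &b,
                          const Vec3 &c) {
    double d1 = (b[i0] - a[i0]) * (p[i1] - a[i1]) -
                (b[i1] - a[i1]) * (p[i0] - a[i0]);
    double d2 = (c[i0] - b[i0]) * (p[i1] - b[i1]) -
                (c[i1] - b[i1]) * (p[i0] - b[i0]);
    double d3 = (a[i0] - c[i0]) * (p[i1] - c[i1]) -
                (a[i1] - c[i1]) * (p[i0] - c[i0]);
    bool has_neg = (d1 < 0) || (d2 < 0) || (d3 < 0);
    bool has_pos = (d1 > 0) || (d2 > 0) || (d3 > 0);
    return !(has_neg && has_pos);
  };
  if (point_in_tri(v0, u0, u1, u2)) return true;
  if (point_in_tri(u0, v0, v1, v2)) return true;
  return false;
}

// proper (positive-length or coplanar-overlap) intersection test; touching
// within eps of a shared plane boundary counts as intersecting only if the
// crossing interval is longer than eps.
inline bool tri_tri_intersect(const Vec3 &v0, const Vec3 &v1, const Vec3 &v2,
                              const Vec3 &u0, const Vec3 &u1, const Vec3 &u2,
                              double eps) {
  Vec3 n1 = cross(v1 - v0, v2 - v0);
  double d1 = -dot(n1, v0);
  double du0 = dot(n1, u0) + d1;
  double du1 = dot(n1, u1) + d1;
  double du2 = dot(n1, u2) + d1;
  if (std::fabs(du0) < eps) du0 = 0;
  if (std::fabs(du1) < eps) du1 = 0;
  if (std::fabs(du2) < eps) du2 = 0;
  double du01 = du0 * du1, du02 = du0 * du2;
  if (du01 > 0 && du02 > 0) return false;  // all on one side

  Vec3 n2 = cross(u1 - u0, u2 - u0);
  double d2 = -dot(n2, u0);
  double dv0 = dot(n2, v0) + d2;
  double dv1 = dot(n2, v1) + d2;
  double dv2 = dot(n2, v2) + d2;
  if (std::fabs(dv0) < eps) dv0 = 0;
  if (std::fabs(dv1) < eps) dv1 = 0;
  if (std::fabs(dv2) < eps) dv2 = 0;
  double dv01 = dv0 * dv1, dv02 = dv0 * dv2;
  if (dv01 > 0 && dv02 > 0) return false;

  Vec3 dline = cross(n1, n2);
  double maxc = std::fabs(dline.x);
  int index = 0;
  if (std::fabs(dline.y) > maxc) { maxc = std::fabs(dline.y); index = 1; }
  if (std::fabs(dline.z) > maxc) { maxc = std::fabs(dline.z); index = 2; }
  if (maxc < eps) {
    if (du0 == 0 && du1 == 0 && du2 == 0)
      return coplanar_tri_tri(n1, v0, v1, v2, u0, u1, u2);
    return false;
  }

  auto interval = [&](double p0, double p1, double p2, double dd0, double dd1,
                      double dd2, double &t1o, double &t2o) -> bool {
    // order so that p0 sits alone on its side
    double a = p0, b = p1, c = p2, x0 = dd0, x1 = dd1, x2 = dd2;
    if (x0 * x1 > 0) { std::swap(a, c); std::swap(x0, x2); }
    else if (x0 * x2 > 0) { std::swap(a, b); std::swap(x0, x1); }
    else if (x1 * x2 > 0 || x0 != 0) {
      // a alone already
    } else if (x1 != 0) { std::swap(a, b); std::swap(x0, x1); }
    else if (x2 != 0) { std::swap(a, c); std::swap(x0, x2); }
    else return false;  // coplanar, handled elsewhere
    double denom1 = x0 - x1, denom2 = x0 - x2;
    t1o = a + (b - a) * (denom1 != 0 ? x0 / denom1 : 0.5);
    t2o = a + (c - a) * (denom2 != 0 ? x0 / denom2 : 0.5);
    return true;
  };

  double vp0 = v0[index], vp1 = v1[index], vp2 = v2[index];
  double up0 = u0[index], up1 = u1[index], up2 = u2[index];
  double s1, s2, t1, t2;
  if (!interval(vp0, vp1, vp2, dv0, dv1, dv2, s1, s2)) return false;
  if (!interval(up0, up1, up2, du0, du1, du2, t1, t2)) return false;
  if (s1 > s2) std::swap(s1, s2);
  if (t1 > t2) std::swap(t1, t2);
  double lo = std::max(s1, t1), hi = std::min(s2, t2);
  return hi - lo > eps;  // require positive overlap length
}

// ---- AABB tree over triangles ----------------------------------------------

struct BVH {
  struct Node {
    AABB box;
    int left, right;    // children, -1 for leaf
    int start, count;   // leaf triangle range in `order`
  };
  std::vector<Node> nodes;
  std::vector<int> order;
  std::vector<AABB> tri_box;
  const double *V;
  const int *T;  // 0-based triangle indices, column-major (nt x 3)
  int nt, nv;

  Vec3 vert(int i) const { return Vec3(V[i], V[i + nv], V[i + 2 * nv]); }
  void tri(int f, Vec3 &a, Vec3 &b, Vec3 &c) const {
    a = vert(T[f]);
    b = vert(T[f + nt]);
    c = vert(T[f + 2 * nt]);
  }

  void build(const double *V_, int nv_, const int *T_, int nt_) {
    V = V_; T = T_; nv = nv_; nt = nt_;
    tri_box.resize(nt);
    order.resize(nt);
    for (int f = 0; f < nt; ++f) {
      order[f] = f;
      Vec3 a, b, c;
      tri(f, a, b, c);
      tri_box[f].expand(a);
      tri_box[f].expand(b);
      tri_box[f].expand(c);
    }
    nodes.clear();
    nodes.reserve(2 * nt);
    if (nt > 0) build_node(0, nt);
  }

  int build_node(int start, int count) {
    int id = (int)nodes.size();
    nodes.push_back(Node());
    AABB box;
    for (int i = start; i < start + count; ++i) box.expand(tri_box[order[i]]);
    nodes[id].box = box;
    if (count <= 4) {
      nodes[id].left = nodes[id].right = -1;
      nodes[id].start = start;
      nodes[id].count = count;
      return id;
    }
    Vec3 ext = box.hi - box.lo;
    int axis = 0;
    if (ext.y > ext.x && ext.y >= ext.z) axis = 1;
    else if (ext.z > ext.x && ext.z > ext.y) axis = 2;
    int mid = start + count / 2;
    std::nth_element(order.begin() + start, order.begin() + mid,
                     order.begin() + start + count,
                     [&](int a, int b) {
                       double ca = tri_box[a].lo[axis] + tri_box[a].hi[axis];
                       double cb = tri_box[b].lo[axis] + tri_box[b].hi[axis];
                       return ca < cb;
                     });
    int l = build_node(start, mid - start);
    int r = build_node(mid, start + count - mid);
    nodes[id].left = l;
    nodes[id].right = r;
    nodes[id].start = -1;
    nodes[id].count = 0;
    return id;
  }

  // count ray crossings for parity tests, restricted to triangle ids in
  // [f_lo, f_hi)
  int ray_crossings(const Vec3 &orig, const Vec3 &dir, int f_lo,
                    int f_hi) const {
    if (nodes.empty()) return 0;
    Vec3 inv(1.0 / dir.x, 1.0 / dir.y, 1.0 / dir.z);
    int count = 0;
    std::vector<int> stack;
    stack.push_back(0);
    while (!stack.empty()) {
      int id = stack.back();
      stack.pop_back();
      const Node &nd = nodes[id];
      // slab test
      double tmin = 0.0, tmax = 1e300;
      bool miss = false;
      for (int a = 0; a < 3; ++a) {
        double lo = (nd.box.lo[a] - orig[a]) * inv[a];
        double hi = (nd.box.hi[a] - orig[a]) * inv[a];
        if (lo > hi) std::swap(lo, hi);
        tmin = std::max(tmin, lo);
        tmax = std::min(tmax, hi);
        if (tmin > tmax) { miss = true; break; }
      }
      if (miss) continue;
      if (nd.left < 0) {
        for (int i = nd.start; i < nd.start + nd.count; ++i) {
          int f = order[i];
          if (f < f_lo || f >= f_hi) continue;
          Vec3 a, b, c;
          tri(f, a, b, c);
          if (ray_tri(orig, dir, a, b, c) > 0) ++count;
        }
      } else {
        stack.push_back(nd.left);
        stack.push_back(nd.right);
      }
    }
    return count;
  }
};

}  // namespace nm

#endif
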