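// Triangle-mesh ray casting behind a median-split AABB hierarchy:
// pinhole depth rendering with z-buffer semantics, parity voxelization,
// point-in-mesh tests, visibility queries and closest-point-on-mesh.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double a, double b, double c) : x(a), y(b), z(c) {}
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
};
inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct Tri { Vec3 a, b, c; int id; };

struct AABB {
  Vec3 lo, hi;
  AABB() : lo(DBL_MAX, DBL_MAX, DBL_MAX), hi(-DBL_MAX, -DBL_MAX, -DBL_MAX) {}
  void grow(const Vec3& p) {
    lo.x = std::min(lo.x, p.x); lo.y = std::min(lo.y, p.y); lo.z = std::min(lo.z, p.z);
    hi.x = std::max(hi.x, p.x); hi.y = std::max(hi.y, p.y); hi.z = std::max(hi.z, p.z);
  }
  void grow(const Tri& t) { grow(t.a); grow(t.b); grow(t.c); }
};

struct Node { AABB box; int left, right, start, count; };  // leaf iff count > 0

class BVH {
public:
  std::vector<Tri> tris;
  std::vector<Node> nodes;

  BVH(const NumericMatrix& V, const IntegerMatrix& F) {
    int m = F.nrow();
    tris.resize((size_t)m);
    for (int f = 0; f < m; ++f) {
      int i = F(f, 0) - 1, j = F(f, 1) - 1, k = F(f, 2) - 1;
      tris[(size_t)f].a = Vec3(V(i, 0), V(i, 1), V(i, 2));
      tris[(size_t)f].b = Vec3(V(j, 0), V(j, 1), V(j, 2));
      tris[(size_t)f].c = Vec3(V(k, 0), V(k, 1), V(k, 2));
      tris[(size_t)f].id = f;
    }
    nodes.reserve((size_t)(2 * m + 2));
    build(0, m);
  }

  // all intersections t along ray o + t*d (t > tmin), unsorted
  void all_hits(const Vec3& o, const Vec3& d, double tmin,
                std::vector<double>& ts) const {
    walk_all(0, o, d, tmin, ts);
  }

  // first hit: returns t or inf; also face id via fid
  double first_hit(const Vec3& o, const Vec3& d, double tmin, int& fid) const {
    double best = DBL_MAX; fid = -1;
    walk_first(0, o, d, tmin, best, fid);
    return best;
  }

private:
  int build(int start, int count) {
    int idx = (int)nodes.size();
    nodes.push_back(Node());
    AABB box;
    for (int i = start; i < start + count; ++i) box.grow(tris[(size_t)i]);
    nodes[(size_t)idx].box = box;
    if (count <= 4) {
      nodes[(size_t)idx].start = start; nodes[(size_t)idx].count = count;
      nodes[(size_t)idx].left = nodes[(size_t)idx].right = -1;
      return idx;
    }
    Vec3 ext = box.hi - box.lo;
    int axis = (ext.x >= ext.y && ext.x >= ext.z) ? 0 : (ext.y >= ext.z ? 1 : 2);
    int mid = start + count / 2;
    std::nth_element(tris.begin() + start, tris.begin() + mid,
                     tris.begin() + start + count,
                     [axis](const Tri& a, const Tri& b) {
                       double ca = axis == 0 ? a.a.x + a.b.x + a.c.x
                                 : axis == 1 ? a.a.y + a.b.y + a.c.y
                                             : a.a.z + a.b.z + a.c.z;
                       double cb = axis == 0 ? b.a.x + b.b.x + b.c.x
                                 : axis == 1 ? b.a.y + b.b.y + b.c.y
                                             : b.a.z + b.b.z + b.c.z;
                       return ca < cb;
                     });
    nodes[(size_t)idx].start = -1; nodes[(size_t)idx].count = 0;
    int l = build(start, mid - start);
    int r = build(mid, start + count - mid);
    nodes[(size_t)idx].left = l; nodes[(size_t)idx].right = r;
    return idx;
  }

  static bool hit_box(const AABB& b, const Vec3& o, const Vec3& inv, double tmax) {
    double t0 = 0.0, t1 = tmax;
    double ta = (b.lo.x - o.x) * inv.x, tb = (b.hi.x - o.x) * inv.x;
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta); t1 = std::min(t1, tb);
    ta = (b.lo.y - o.y) * inv.y; tb = (b.hi.y - o.y) * inv.y;
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta); t1 = std::min(t1, tb);
    ta = (b.lo.z - o.z) * inv.z; tb = (b.hi.z - o.z) * inv.z;
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta); t1 = std::min(t1, tb);
    return t0 <= t1;
  }

  // Moller-Trumbore with unnormalised direction
  static bool hit_tri(const Tri& tr, const Vec3& o, const Vec3& d,
                      double tmin, double& t) {
    Vec3 e1 = tr.b - tr.a, e2 = tr.c - tr.a;
    Vec3 p = cross(d, e2);
    double det = dot(e1, p);
    if (std::fabs(det) < 1e-14) return false;
    double inv = 1.0 / det;
    Vec3 s = o - tr.a;
    double u = dot(s, p) * inv;
    if (u < 0.0 || u > 1.0) return false;
    Vec3 q = cross(s, e1);
    double v = dot(d, q) * inv;
    if (v < 0.0 || u + v > 1.0) return false;
    double tt = dot(e2, q) * inv;
    if (tt <= tmin) return false;
    t = tt;
    return true;
  }

  static inline double safe_inv(double x) {
    return 1.0 / (std::fabs(x) < 1e-30 ? (x < 0 ? -1e-30 : 1e-30) : x);
  }

  void walk_all(int ni, const Vec3& o, const Vec3& d, double tmin,
                std::vector<double>& ts) const {
    const Node& nd = nodes[(size_t)ni];
    Vec3 inv(safe_inv(d.x), safe_inv(d.y), safe_inv(d.z));
    if (!hit_box(nd.box, o, inv, DBL_MAX)) return;
    if (nd.count > 0) {
      double t;
      for (int i = nd.start; i < nd.start + nd.count; ++i)
        if (hit_tri(tris[(size_t)i], o, d, tmin, t)) ts.push_back(t);
      return;
    }
    walk_all(nd.left, o, d, tmin, ts);
    walk_all(nd.right, o, d, tmin, ts);
  }

  void walk_first(int ni, const Vec3& o, const Vec3& d, double tmin,
                  double& best, int& fid) const {
    const Node& nd = nodes[(size_t)ni];
    Vec3 inv(safe_inv(d.x), safe_inv(d.y), safe_inv(d.z));
    if (!hit_box(nd.box, o, inv, best)) return;
    if (nd.count > 0) {
      double t;
      for (int i = nd.start; i < nd.start + nd.count; ++i)
        if (hit_tri(tris[(size_t)i], o, d, tmin, t) && t < best) {
          best = t; fid = tris[(size_t)i].id;
        }
      return;
    }
    walk_first(nd.left, o, d, tmin, best, fid);
    walk_first(nd.right, o, d, tmin, best, fid);
  }
};

// parity of the number of intersections beyond the query point along +x
bool inside_parity(const BVH& bvh, const Vec3& p) {
  std::vector<double> ts;
  bvh.all_hits(p, Vec3(1.0, 0.0, 0.0), 1e-9, ts);
  if (ts.empty()) return false;
  std::sort(ts.begin(), ts.end());
  int count = 0;
  double last = -DBL_MAX;
  for (double t : ts) {
    if (t - last > 1e-9) ++count;  // collapse duplicate edge hits
    last = t;
  }
  return (count % 2) == 1;
}

}  // namespace

// Depth image: pixel (row v, col u) casts direction
// R_cam2world * ((u - cx)/fx, (v - cy)/fy, 1) from the camera origin;
// the ray parameter equals depth along camera z. Invalid pixels are 0.
// [[Rcpp::export]]
NumericMatrix cpp_render_depth(NumericMatrix V, IntegerMatrix F,
                               int width, int height,
                               double fx, double fy, double cx, double cy,
                               NumericMatrix Rcw, NumericVector tcw,
                               double max_range) {
  BVH bvh(V, F);
  NumericMatrix img(height, width);
  Vec3 o(tcw[0], tcw[1], tcw[2]);
  for (int v = 0; v < height; ++v) {
    for (int u = 0; u < width; ++u) {
      double dx = (u - cx) / fx, dy = (v - cy) / fy;
      Vec3 d(Rcw(0, 0) * dx + Rcw(0, 1) * dy + Rcw(0, 2),
             Rcw(1, 0) * dx + Rcw(1, 1) * dy + Rcw(1, 2),
             Rcw(2, 0) * dx + Rcw(2, 1) * dy + Rcw(2, 2));
      int fid;
      double t = bvh.first_hit(o, d, 1e-9, fid);
      img(v, u) = (fid >= 0 && t <= max_range) ? t : 0.0;
    }
  }
  return img;
}

// Occupancy of voxel centres origin + (i,j,k)*spacing for a watertight
// mesh, by x-ray parity per (j,k) row.
// [[Rcpp::export]]
LogicalVector cpp_voxelize_parity(NumericMatrix V, IntegerMatrix F,
                                  NumericVector origin, NumericVector spacing,
                                  IntegerVector dims) {
  BVH bvh(V, F);
  int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  double x0 = origin[0] - 10.0 * spacing[0];
  std::vector<double> ts;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      Vec3 o(x0, origin[1] + j * spacing[1], origin[2] + k * spacing[2]);
      ts.clear();
      bvh.all_hits(o, Vec3(1.0, 0.0, 0.0), 0.0, ts);
      if (ts.empty()) continue;
      std::sort(ts.begin(), ts.end());
      std::vector<double> uniq;
      for (double t : ts)
        if (uniq.empty() || t - uniq.back() > 1e-9) uniq.push_back(t);
      // inside between hit 2m and 2m+1
      for (size_t m = 0; m + 1 < uniq.size(); m += 2) {
        double xa = x0 + uniq[m], xb = x0 + uniq[m + 1];
        int ia = (int)std::ceil((xa - origin[0]) / spacing[0] - 1e-12);
        int ib = (int)std::floor((xb - origin[0]) / spacing[0] + 1e-12);
        ia = std::max(ia, 0); ib = std::min(ib, nx - 1);
        for (int i = ia; i <= ib; ++i)
          out[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix V, IntegerMatrix F,
                                 NumericMatrix Q) {
  BVH bvh(V, F);
  int m = Q.nrow();
  LogicalVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = inside_parity(bvh, Vec3(Q(i, 0), Q(i, 1), Q(i, 2)));
  return out;
}

// Visibility of sample points from an eye position (occlusion only; the
// caller applies any frustum test).
// [[Rcpp::export]]
LogicalVector cpp_points_visible(NumericMatrix V, IntegerMatrix F,
                                 NumericMatrix S, NumericVector eye,
                                 double tol) {
  BVH bvh(V, F);
  int m = S.nrow();
  LogicalVector out(m);
  Vec3 o(eye[0], eye[1], eye[2]);
  for (int i = 0; i < m; ++i) {
    Vec3 p(S(i, 0), S(i, 1), S(i, 2));
    Vec3 d = p - o;
    int fid;
    double t = bvh.first_hit(o, d, 1e-9, fid);
    out[i] = (fid < 0) || (t >= 1.0 - tol);  // param 1 is the point itself
  }
  return out;
}

// Closest point on any triangle (Ericson's point-triangle projection),
// exhaustive over faces per query.
static Vec3 closest_on_tri(const Vec3& p, const Vec3& a, const Vec3& b,
                           const Vec3& c) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return a + ab * v;
  }
  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + ab * v + ac * w;
}

// [[Rcpp::export]]
List cpp_closest_point_mesh(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  int m = Q.nrow(), nf = F.nrow();
  NumericMatrix pts(m, 3);
  NumericVector dist(m);
  std::vector<Vec3> a((size_t)nf), b((size_t)nf), c((size_t)nf);
  for (int f = 0; f < nf; ++f) {
    int i = F(f, 0) - 1, j = F(f, 1) - 1, k = F(f, 2) - 1;
    a[(size_t)f] = Vec3(V(i, 0), V(i, 1), V(i, 2));
    b[(size_t)f] = Vec3(V(j, 0), V(j, 1), V(j, 2));
    c[(size_t)f] = Vec3(V(k, 0), V(k, 1), V(k, 2));
  }
  for (int q = 0; q < m; ++q) {
    Vec3 p(Q(q, 0), Q(q, 1), Q(q, 2));
    double best = DBL_MAX;
    Vec3 bp;
    for (int f = 0; f < nf; ++f) {
      Vec3 cp = closest_on_tri(p, a[(size_t)f], b[(size_t)f], c[(size_t)f]);
      double d = dot(cp - p, cp - p);
      if (d < best) { best = d; bp = cp; }
    }
    pts(q, 0) = bp.x; pts(q, 1) = bp.y; pts(q, 2) = bp.z;
    dist[q] = std::sqrt(best);
  }
  return List::create(_["point"] = pts, _["distance"] = dist);
}
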