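// Surface simplification by quadric-error-metric edge collapse
// (Garland-Heckbert): per-vertex plane quadrics, a lazy min-heap of
// collapse candidates, link-condition and normal-flip guards.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Quadric {
  // symmetric 4x4: a11 a12 a13 a14 a22 a23 a24 a33 a34 a44
  double q[10];
  Quadric() { std::fill(q, q + 10, 0.0); }
  void add_plane(double a, double b, double c, double d) {
    q[0] += a * a; q[1] += a * b; q[2] += a * c; q[3] += a * d;
    q[4] += b * b; q[5] += b * c; q[6] += b * d;
    q[7] += c * c; q[8] += c * d; q[9] += d * d;
  }
  Quadric operator+(const Quadric& o) const {
    Quadric r;
    for (int i = 0; i < 10; ++i) r.q[i] = q[i] + o.q[i];
    return r;
  }
  double eval(double x, double y, double z) const {
    return q[0] * x * x + 2 * q[1] * x * y + 2 * q[2] * x * z + 2 * q[3] * x +
           q[4] * y * y + 2 * q[5] * y * z + 2 * q[6] * y +
           q[7] * z * z + 2 * q[8] * z + q[9];
  }
  // minimiser of the quadric; false if the 3x3 system is near-singular
  bool optimum(double& x, double& y, double& z) const {
    double a11 = q[0], a12 = q[1], a13 = q[2], a22 = q[4], a23 = q[5], a33 = q[7];
    double det = a11 * (a22 * a33 - a23 * a23) - a12 * (a12 * a33 - a23 * a13) +
                 a13 * (a12 * a23 - a22 * a13);
    double scale = std::max({std::fabs(a11), std::fabs(a22), std::fabs(a33), 1e-12});
    if (std::fabs(det) < 1e-9 * scale * scale * scale) return false;
    double b1 = -q[3], b2 = -q[6], b3 = -q[8];
    x = (b1 * (a22 * a33 - a23 * a23) - a12 * (b2 * a33 - a23 * b3) +
         a13 * (b2 * a23 - a22 * b3)) / det;
    y = (a11 * (b2 * a33 - a23 * b3) - b1 * (a12 * a33 - a13 * a23) +
         a13 * (a12 * b3 - b2 * a13)) / det;
    z = (a11 * (a22 * b3 - b2 * a23) - a12 * (a12 * b3 - b2 * a13) +
         b1 * (a12 * a23 - a22 * a13)) / det;
    return true;
  }
};

struct Cand {
  double cost;
  int v1, v2;
  uint64_t stamp;  // version sum at push time
  bool operator<(const Cand& o) const { return cost > o.cost; }  // min-heap
};

}  // namespace

// [[Rcpp::export]]
List cpp_decimate_qem(NumericMatrix Vin, IntegerMatrix Fin, int target_faces) {
  int n = Vin.nrow(), m = Fin.nrow();
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) { X[i] = Vin(i, 0); Y[i] = Vin(i, 1); Z[i] = Vin(i, 2); }
  std::vector<std::array<int, 3> > F((size_t)m);
  for (int f = 0; f < m; ++f)
    F[(size_t)f] = {Fin(f, 0) - 1, Fin(f, 1) - 1, Fin(f, 2) - 1};
  std::vector<char> valive((size_t)n, 1), falive((size_t)m, 1);
  std::vector<uint64_t> version((size_t)n, 0);
  std::vector<Quadric> Q((size_t)n);
  std::vector<std::vector<int> > vfaces((size_t)n);

  auto face_normal = [&](int f, double& a, double& b, double& c) -> double {
    const auto& t = F[(size_t)f];
    double ux = X[t[1]] - X[t[0]], uy = Y[t[1]] - Y[t[0]], uz = Z[t[1]] - Z[t[0]];
    double wx = X[t[2]] - X[t[0]], wy = Y[t[2]] - Y[t[0]], wz = Z[t[2]] - Z[t[0]];
    a = uy * wz - uz * wy; b = uz * wx - ux * wz; c = ux * wy - uy * wx;
    double len = std::sqrt(a * a + b * b + c * c);
    if (len > 1e-300) { a /= len; b /= len; c /= len; }
    return len;
  };

  for (int f = 0; f < m; ++f) {
    double a, b, c;
    double len = face_normal(f, a, b, c);
    if (len < 1e-300) { falive[(size_t)f] = 0; continue; }
    const auto& t = F[(size_t)f];
    double d = -(a * X[t[0]] + b * Y[t[0]] + c * Z[t[0]]);
    for (int v = 0; v < 3; ++v) {
      Q[(size_t)t[v]].add_plane(a, b, c, d);
      vfaces[(size_t)t[v]].push_back(f);
    }
  }
  int nfaces = 0;
  for (int f = 0; f < m; ++f) if (falive[(size_t)f]) ++nfaces;

  std::priority_queue<Cand> heap;
  auto push_edge = [&](int v1, int v2) {
    if (v1 > v2) std::swap(v1, v2);
    Quadric s = Q[(size_t)v1] + Q[(size_t)v2];
    double x, y, z;
    if (!s.optimum(x, y, z)) {
      double mx = 0.5 * (X[v1] + X[v2]), my = 0.5 * (Y[v1] + Y[v2]),
             mz = 0.5 * (Z[v1] + Z[v2]);
      double c1 = s.eval(X[v1], Y[v1], Z[v1]), c2 = s.eval(X[v2], Y[v2], Z[v2]),
             cm = s.eval(mx, my, mz);
      if (cm <= c1 && cm <= c2) { x = mx; y = my; z = mz; }
      else if (c1 <= c2) { x = X[v1]; y = Y[v1]; z = Z[v1]; }
      else { x = X[v2]; y = Y[v2]; z = Z[v2]; }
    }
    Cand c;
    c.cost = s.eval(x, y, z);
    c.v1 = v1; c.v2 = v2;
    c.stamp = version[(size_t)v1] + version[(size_t)v2];
    heap.push(c);
  };

  for (int f = 0; f < m; ++f) {
    if (!falive[(size_t)f]) continue;
    const auto& t = F[(size_t)f];
    for (int e = 0; e < 3; ++e) {
      int a = t[e], b = t[(e + 1) % 3];
      if (a < b) push_edge(a, b);
    }
  }

  auto neighbors = [&](int v) {
    std::vector<int> nb;
    for (int f : vfaces[(size_t)v]) {
      if (!falive[(size_t)f]) continue;
      for (int w : F[(size_t)f]) if (w != v) nb.push_back(w);
    }
    std::sort(nb.begin(), nb.end());
    nb.erase(std::unique(nb.begin(), nb.end()), nb.end());
    return nb;
  };

  while (nfaces > target_faces && !heap.empty()) {
    Cand c = heap.top();
    heap.pop();
    int v1 = c.v1, v2 = c.v2;
    if (!valive[(size_t)v1] || !valive[(size_t)v2]) continue;
    if (c.stamp != version[(size_t)v1] + version[(size_t)v2]) continue;
    // shared faces of the edge
    std::vector<int> shared;
    for (int f : vfaces[(size_t)v1]) {
      if (!falive[(size_t)f]) continue;
      const auto& t = F[(size_t)f];
      if (t[0] == v2 || t[1] == v2 || t[2] == v2) shared.push_back(f);
    }
    if (shared.empty()) continue;  // stale edge
    // link condition: common neighbours must be exactly the apexes of shared faces
    std::vector<int> nb1 = neighbors(v1), nb2 = neighbors(v2), common;
    std::set_intersection(nb1.begin(), nb1.end(), nb2.begin(), nb2.end(),
                          std::back_inserter(common));
    if ((int)common.size() != (int)shared.size()) continue;

    // target position
    Quadric s = Q[(size_t)v1] + Q[(size_t)v2];
    double x, y, z;
    if (!s.optimum(x, y, z)) { x = 0.5 * (X[v1] + X[v2]); y = 0.5 * (Y[v1] + Y[v2]); z = 0.5 * (Z[v1] + Z[v2]); }

    // normal-flip guard on surviving faces
    double ox1 = X[v1], oy1 = Y[v1], oz1 = Z[v1];
    double ox2 = X[v2], oy2 = Y[v2], oz2 = Z[v2];
    bool flip = false;
    for (int pass = 0; pass < 2 && !flip; ++pass) {
      int v = pass == 0 ? v1 : v2;
      for (int f : vfaces[(size_t)v]) {
        if (!falive[(size_t)f]) continue;
        const auto& t = F[(size_t)f];
        if ((t[0] == v1 || t[1] == v1 || t[2] == v1) &&
            (t[0] == v2 || t[1] == v2 || t[2] == v2)) continue;  // dies anyway
        double a0, b0, c0;
        if (face_normal(f, a0, b0, c0) < 1e-300) continue;
        X[v1] = X[v2] = x; Y[v1] = Y[v2] = y; Z[v1] = Z[v2] = z;
        double a1, b1, c1;
        double len = face_normal(f, a1, b1, c1);
        X[v1] = ox1; Y[v1] = oy1; Z[v1] = oz1;
        X[v2] = ox2; Y[v2] = oy2; Z[v2] = oz2;
        if (len < 1e-300 || a0 * a1 + b0 * b1 + c0 * c1 < 0.0) { flip = true; break; }
      }
    }
    if (flip) continue;

    // perform the collapse: v2 -> v1 at (x,y,z)
    X[v1] = x; Y[v1] = y; Z[v1] = z;
    Q[(size_t)v1] = s;
    for (int f : shared) { falive[(size_t)f] = 0; --nfaces; }
    for (int f : vfaces[(size_t)v2]) {
      if (!falive[(size_t)f]) continue;
      auto& t = F[(size_t)f];
      for (int e = 0; e < 3; ++e) if (t[e] == v2) t[e] = v1;
      vfaces[(size_t)v1].push_back(f);
    }
    valive[(size_t)v2] = 0;
    // only the merged vertex's quadric/position changed: bumping its version
    // invalidates exactly the stale heap entries, and ring-internal edges
    // (whose endpoint quadrics are untouched) stay valid
    ++version[(size_t)v1];
    ++version[(size_t)v2];
    for (int w : neighbors(v1)) push_edge(v1, w);
  }

  // compact
  std::vector<int> remap((size_t)n, -1);
  int nv = 0;
  for (int i = 0; i < n; ++i) if (valive[(size_t)i]) remap[(size_t)i] = nv++;
  NumericMatrix Vout(nv, 3);
  for (int i = 0; i < n; ++i)
    if (remap[(size_t)i] >= 0) {
      Vout(remap[(size_t)i], 0) = X[i];
      Vout(remap[(size_t)i], 1) = Y[i];
      Vout(remap[(size_t)i], 2) = Z[i];
    }
  std::vector<std::array<int, 3> > fout;
  for (int f = 0; f < m; ++f) {
    if (!falive[(size_t)f]) continue;
    const auto& t = F[(size_t)f];
    if (t[0] == t[1] || t[1] == t[2] || t[0] == t[2]) continue;
    fout.push_back({remap[(size_t)t[0]] + 1, remap[(size_t)t[1]] + 1,
                    remap[(size_t)t[2]] + 1});
  }
  IntegerMatrix Fout((int)fout.size(), 3);
  for (size_t f = 0; f < fout.size(); ++f) {
    Fout((int)f, 0) = fout[f][0]; Fout((int)f, 1) = fout[f][1]; Fout((int)f, 2) = fout[f][2];
  }
  return List::create(_["vertices"] = Vout, _["faces"] = Fout);
}
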