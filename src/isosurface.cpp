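// Iso-surface extraction by marching tetrahedra on the Kuhn 6-tet cube
// decomposition. The split is translation-invariant, so shared cube faces
// carry the same diagonal in both neighbouring cells and the extracted
// surface of a bounded region is closed. Edge vertices are deduplicated
// through a global edge-key map, so the mesh is vertex-welded.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;
  const double* field;
  int nx, ny, nz;
  double iso;
  double ox, oy, oz, sx, sy, sz;

  inline double val(int i, int j, int k) const {
    return field[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
  }
  inline uint64_t gid(int i, int j, int k) const {
    return (uint64_t)i + (uint64_t)nx * ((uint64_t)j + (uint64_t)ny * (uint64_t)k);
  }

  // vertex on edge between grid points g1, g2 (linear interpolation)
  int edge_point(int i1, int j1, int k1, int i2, int j2, int k2) {
    uint64_t a = gid(i1, j1, k1), b = gid(i2, j2, k2);
    uint64_t key = a < b ? (a << 32 | b) : (b << 32 | a);
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double f1 = val(i1, j1, k1), f2 = val(i2, j2, k2);
    double t = (std::fabs(f2 - f1) < 1e-15) ? 0.5 : (iso - f1) / (f2 - f1);
    if (t < 0) t = 0; if (t > 1) t = 1;
    vx.push_back(ox + sx * (i1 + t * (i2 - i1)));
    vy.push_back(oy + sy * (j1 + t * (j2 - j1)));
    vz.push_back(oz + sz * (k1 + t * (k2 - k1)));
    int id = (int)vx.size() - 1;
    edge_vertex[key] = id;
    return id;
  }

  // orient triangle (p,q,r) so its normal points away from the inside
  // (high-field) side, represented by reference point (rx,ry,rz)
  void add_tri(int p, int q, int r, double rx, double ry, double rz) {
    double ux = vx[(size_t)q] - vx[(size_t)p], uy = vy[(size_t)q] - vy[(size_t)p],
           uz = vz[(size_t)q] - vz[(size_t)p];
    double wx = vx[(size_t)r] - vx[(size_t)p], wy = vy[(size_t)r] - vy[(size_t)p],
           wz = vz[(size_t)r] - vz[(size_t)p];
    double nxv = uy * wz - uz * wy, nyv = uz * wx - ux * wz,
           nzv = ux * wy - uy * wx;
    double cxv = (vx[(size_t)p] + vx[(size_t)q] + vx[(size_t)r]) / 3.0 - rx;
    double cyv = (vy[(size_t)p] + vy[(size_t)q] + vy[(size_t)r]) / 3.0 - ry;
    double czv = (vz[(size_t)p] + vz[(size_t)q] + vz[(size_t)r]) / 3.0 - rz;
    if (nxv * cxv + nyv * cyv + nzv * czv < 0) std::swap(q, r);
    fa.push_back(p + 1); fb.push_back(q + 1); fc.push_back(r + 1);
  }

  void do_tet(const int t[4][3]) {
    double f[4];
    bool in[4];
    int nin = 0;
    for (int v = 0; v < 4; ++v) {
      f[v] = val(t[v][0], t[v][1], t[v][2]);
      in[v] = f[v] >= iso;
      if (in[v]) ++nin;
    }
    if (nin == 0 || nin == 4) return;
    // reference point: centroid of inside corners (in world coords)
    double rx = 0, ry = 0, rz = 0;
    for (int v = 0; v < 4; ++v)
      if (in[v]) {
        rx += ox + sx * t[v][0]; ry += oy + sy * t[v][1]; rz += oz + sz * t[v][2];
      }
    rx /= nin; ry /= nin; rz /= nin;
    if (nin == 1 || nin == 3) {
      int odd = -1;
      for (int v = 0; v < 4; ++v)
        if (in[v] == (nin == 1)) odd = v;
      int e[3], c = 0;
      for (int v = 0; v < 4; ++v) {
        if (v == odd) continue;
        e[c++] = edge_point(t[odd][0], t[odd][1], t[odd][2],
                            t[v][0], t[v][1], t[v][2]);
      }
      add_tri(e[0], e[1], e[2], rx, ry, rz);
    } else {  // 2 in, 2 out -> quad
      int ins[2], outs[2], ci = 0, co = 0;
      for (int v = 0; v < 4; ++v) (in[v] ? ins[ci++] : outs[co++]) = v;
      int e00 = edge_point(t[ins[0]][0], t[ins[0]][1], t[ins[0]][2],
                           t[outs[0]][0], t[outs[0]][1], t[outs[0]][2]);
      int e01 = edge_point(t[ins[0]][0], t[ins[0]][1], t[ins[0]][2],
                           t[outs[1]][0], t[outs[1]][1], t[outs[1]][2]);
      int e10 = edge_point(t[ins[1]][0], t[ins[1]][1], t[ins[1]][2],
                           t[outs[0]][0], t[outs[0]][1], t[outs[0]][2]);
      int e11 = edge_point(t[ins[1]][0], t[ins[1]][1], t[ins[1]][2],
                           t[outs[1]][0], t[outs[1]][1], t[outs[1]][2]);
      // quad cycle e00 -> e01 -> e11 -> e10
      add_tri(e00, e01, e11, rx, ry, rz);
      add_tri(e00, e11, e10, rx, ry, rz);
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_isosurface(NumericVector field, IntegerVector dims, double iso,
                    NumericVector origin, NumericVector spacing) {
  MTState st;
  st.field = field.begin();
  st.nx = dims[0]; st.ny = dims[1]; st.nz = dims[2];
  st.iso = iso;
  st.ox = origin[0]; st.oy = origin[1]; st.oz = origin[2];
  st.sx = spacing[0]; st.sy = spacing[1]; st.sz = spacing[2];

  // Kuhn decomposition: for each axis permutation, the tet
  // (0,0,0) -> +perm[0] -> +perm[1] -> +perm[2] ending at (1,1,1)
  static const int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                                  {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
  for (int k = 0; k + 1 < st.nz; ++k)
    for (int j = 0; j + 1 < st.ny; ++j)
      for (int i = 0; i + 1 < st.nx; ++i) {
        // skip cubes entirely inside or outside the iso-level
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          double f = st.val(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1));
          if (f >= iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int p = 0; p < 6; ++p) {
          int tet[4][3] = {{i, j, k}, {0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
          int cur[3] = {i, j, k};
          for (int s = 0; s < 3; ++s) {
            cur[perms[p][s]] += 1;
            tet[s + 1][0] = cur[0]; tet[s + 1][1] = cur[1]; tet[s + 1][2] = cur[2];
          }
          st.do_tet(tet);
        }
      }

  int nv = (int)st.vx.size(), nf = (int)st.fa.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = st.vx[(size_t)i]; V(i, 1) = st.vy[(size_t)i]; V(i, 2) = st.vz[(size_t)i];
  }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = st.fa[(size_t)i]; F(i, 1) = st.fb[(size_t)i]; F(i, 2) = st.fc[(size_t)i];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
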