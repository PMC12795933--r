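// Brute-force nearest-neighbour queries on mm-scale point sets.
// Clouds entering registration are voxel-downsampled to a few thousand
// points, where exhaustive search is faster than tree construction and,
// with the lowest-index tie-break, fully deterministic.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double sqdist(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// Copy an n x 3 matrix into row-major contiguous storage.
static std::vector<double> rows3(const NumericMatrix& m) {
  int n = m.nrow();
  std::vector<double> out(3 * (size_t)n);
  for (int i = 0; i < n; ++i) {
    out[3 * (size_t)i]     = m(i, 0);
    out[3 * (size_t)i + 1] = m(i, 1);
    out[3 * (size_t)i + 2] = m(i, 2);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_knn(NumericMatrix data, NumericMatrix query, int k) {
  int n = data.nrow(), m = query.nrow();
  if (k > n) stop("k exceeds number of data points");
  std::vector<double> D = rows3(data), Q = rows3(query);
  IntegerMatrix idx(m, k);
  NumericMatrix dist(m, k);
  std::vector<std::pair<double, int> > cand((size_t)n);
  for (int q = 0; q < m; ++q) {
    const double* qp = &Q[3 * (size_t)q];
    for (int i = 0; i < n; ++i)
      cand[(size_t)i] = std::make_pair(sqdist(qp, &D[3 * (size_t)i]), i);
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int j = 0; j < k; ++j) {
      idx(q, j) = cand[(size_t)j].second + 1;  // 1-based for R
      dist(q, j) = std::sqrt(cand[(size_t)j].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Nearest single neighbour via an exact uniform-grid search with
// expanding cell rings; ties broken toward the lowest index.
// [[Rcpp::export]]
List cpp_nn1(NumericMatrix data, NumericMatrix query) {
  int n = data.nrow(), m = query.nrow();
  std::vector<double> D = rows3(data), Q = rows3(query);
  IntegerVector idx(m);
  NumericVector dist(m);
  // grid setup: ~1 point per cell on average
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      double v = D[3 * (size_t)i + c];
      if (v < lo[c]) lo[c] = v;
      if (v > hi[c]) hi[c] = v;
    }
  double ext = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1e-9});
  double cell = std::max(ext / std::max(1.0, std::cbrt((double)n)), 1e-9);
  int g[3];
  for (int c = 0; c < 3; ++c)
    g[c] = std::max(1, (int)std::floor((hi[c] - lo[c]) / cell) + 1);
  auto cell_of = [&](const double* p, int* out) {
    for (int c = 0; c < 3; ++c) {
      int v = (int)std::floor((p[c] - lo[c]) / cell);
      out[c] = std::min(std::max(v, 0), g[c] - 1);
    }
  };
  std::vector<std::vector<int> > buckets((size_t)g[0] * g[1] * g[2]);
  for (int i = 0; i < n; ++i) {
    int cc[3];
    cell_of(&D[3 * (size_t)i], cc);
    buckets[(size_t)cc[0] + (size_t)g[0] * (cc[1] + (size_t)g[1] * cc[2])]
        .push_back(i);
  }
  for (int q = 0; q < m; ++q) {
    const double* qp = &Q[3 * (size_t)q];
    int cc[3];
    cell_of(qp, cc);
    double best = R_PosInf;
    int bi = 0;
    int max_ring = std::max({g[0], g[1], g[2]});
    for (int ring = 0; ring <= max_ring; ++ring) {
      // stop once no point in this or any farther ring can beat the best:
      // every point of ring r is at least (r-1)*cell from the query cell
      if (std::isfinite(best)) {
        double bound = std::max(0.0, (double)(ring - 1)) * cell;
        if (bound * bound > best) break;
      }
      bool any_cell = false;
      int i0 = cc[0] - ring, i1 = cc[0] + ring;
      int j0 = cc[1] - ring, j1 = cc[1] + ring;
      int k0 = cc[2] - ring, k1 = cc[2] + ring;
      for (int kk = k0; kk <= k1; ++kk) {
        if (kk < 0 || kk >= g[2]) continue;
        for (int jj = j0; jj <= j1; ++jj) {
          if (jj < 0 || jj >= g[1]) continue;
          for (int ii = i0; ii <= i1; ++ii) {
            if (ii < 0 || ii >= g[0]) continue;
            // only the shell of the ring
            if (ring > 0 && ii != i0 && ii != i1 && jj != j0 && jj != j1 &&
                kk != k0 && kk != k1)
              continue;
            any_cell = true;
            const std::vector<int>& b =
                buckets[(size_t)ii + (size_t)g[0] * (jj + (size_t)g[1] * kk)];
            for (int i : b) {
              double d = sqdist(qp, &D[3 * (size_t)i]);
              if (d < best || (d == best && i < bi)) { best = d; bi = i; }
            }
          }
        }
      }
      if (!any_cell && ring > max_ring) break;
    }
    idx[q] = bi + 1;
    dist[q] = std::sqrt(best);
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// All neighbours within radius (self excluded), ascending index order.
// [[Rcpp::export]]
List cpp_radius_nn(NumericMatrix data, double radius) {
  int n = data.nrow();
  std::vector<double> D = rows3(data);
  double r2 = radius * radius;
  List out(n);
  std::vector<int> buf;
  for (int i = 0; i < n; ++i) {
    buf.clear();
    const double* pi = &D[3 * (size_t)i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (sqdist(pi, &D[3 * (size_t)j]) <= r2) buf.push_back(j + 1);
    }
    out[i] = IntegerVector(buf.begin(), buf.end());
  }
  return out;
}
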