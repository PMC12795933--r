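// Binary-mask morphology on voxel grids: largest 26-connected component
// and internal-cavity filling (flood fill of the 6-connected background
// from the volume border, then inversion).
#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// [[Rcpp::export]]
LogicalVector cpp_largest_component26(LogicalVector mask, IntegerVector dims) {
  int64_t nx = dims[0], ny = dims[1], nz = dims[2], n = nx * ny * nz;
  std::vector<int32_t> label((size_t)n, 0);
  std::vector<int64_t> stack;
  int32_t ncomp = 0;
  int64_t best_size = 0;
  int32_t best_label = 0;
  for (int64_t s = 0; s < n; ++s) {
    if (!mask[s] || label[(size_t)s]) continue;
    ++ncomp;
    int64_t size = 0;
    stack.push_back(s);
    label[(size_t)s] = ncomp;
    while (!stack.empty()) {
      int64_t cur = stack.back();
      stack.pop_back();
      ++size;
      int64_t i = cur % nx, j = (cur / nx) % ny, k = cur / (nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int64_t ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            int64_t nb = ii + nx * (jj + ny * kk);
            if (mask[nb] && !label[(size_t)nb]) {
              label[(size_t)nb] = ncomp;
              stack.push_back(nb);
            }
          }
    }
    if (size > best_size) { best_size = size; best_label = ncomp; }
  }
  LogicalVector out(n);
  for (int64_t s = 0; s < n; ++s) out[s] = (label[(size_t)s] == best_label) && best_label;
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dims) {
  int64_t nx = dims[0], ny = dims[1], nz = dims[2], n = nx * ny * nz;
  std::vector<char> outside((size_t)n, 0);
  std::vector<int64_t> stack;
  // seed from every border voxel that is background
  for (int64_t k = 0; k < nz; ++k)
    for (int64_t j = 0; j < ny; ++j)
      for (int64_t i = 0; i < nx; ++i) {
        if (i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1)
          continue;
        int64_t s = i + nx * (j + ny * k);
        if (!mask[s] && !outside[(size_t)s]) {
          outside[(size_t)s] = 1;
          stack.push_back(s);
        }
      }
  const int64_t off_i[6] = {-1, 1, 0, 0, 0, 0};
  const int64_t off_j[6] = {0, 0, -1, 1, 0, 0};
  const int64_t off_k[6] = {0, 0, 0, 0, -1, 1};
  while (!stack.empty()) {
    int64_t cur = stack.back();
    stack.pop_back();
    int64_t i = cur % nx, j = (cur / nx) % ny, k = cur / (nx * ny);
    for (int d = 0; d < 6; ++d) {
      int64_t ii = i + off_i[d], jj = j + off_j[d], kk = k + off_k[d];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      int64_t nb = ii + nx * (jj + ny * kk);
      if (!mask[nb] && !outside[(size_t)nb]) {
        outside[(size_t)nb] = 1;
        stack.push_back(nb);
      }
    }
  }
  LogicalVector out(n);
  for (int64_t s = 0; s < n; ++s) out[s] = !outside[(size_t)s];
  out.attr("dim") = dims;
  return out;
}
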