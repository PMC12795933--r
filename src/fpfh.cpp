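// Local surface descriptors for global registration: covariance normals
// and 33-bin fast point feature histograms (3 x 11 angle histograms).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Normals from the smallest eigenvector of the k-neighbourhood covariance,
// oriented toward `viewpoint`. A neighbourhood whose two smallest
// eigenvalues are both ~0 (collinear points) yields an invalid normal.
// [[Rcpp::export]]
List cpp_estimate_normals(const arma::mat& P, int k, const arma::vec& viewpoint) {
  int n = P.n_rows;
  if (k > n) stop("k exceeds number of points");
  arma::mat N(n, 3, arma::fill::zeros);
  LogicalVector valid(n);
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; ++i) { X[i] = P(i, 0); Y[i] = P(i, 1); Z[i] = P(i, 2); }
  std::vector<std::pair<double, int> > cand((size_t)n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double dx = X[j] - X[i], dy = Y[j] - Y[i], dz = Z[j] - Z[i];
      cand[(size_t)j] = std::make_pair(dx * dx + dy * dy + dz * dz, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    double mx = 0, my = 0, mz = 0;
    for (int s = 0; s < k; ++s) {
      int j = cand[(size_t)s].second;
      mx += X[j]; my += Y[j]; mz += Z[j];
    }
    mx /= k; my /= k; mz /= k;
    double cxx = 0, cxy = 0, cxz = 0, cyy = 0, cyz = 0, czz = 0;
    for (int s = 0; s < k; ++s) {
      int j = cand[(size_t)s].second;
      double dx = X[j] - mx, dy = Y[j] - my, dz = Z[j] - mz;
      cxx += dx * dx; cxy += dx * dy; cxz += dx * dz;
      cyy += dy * dy; cyz += dy * dz; czz += dz * dz;
    }
    arma::mat C = {{cxx, cxy, cxz}, {cxy, cyy, cyz}, {cxz, cyz, czz}};
    C /= k;
    arma::vec eval; arma::mat evec;
    arma::eig_sym(eval, evec, C);
    // eig_sym returns ascending eigenvalues
    bool ok = eval(1) > 1e-12 * std::max(eval(2), 1e-300);
    arma::vec nrm = evec.col(0);
    double dvp = nrm(0) * (viewpoint(0) - X[i]) + nrm(1) * (viewpoint(1) - Y[i]) +
                 nrm(2) * (viewpoint(2) - Z[i]);
    if (dvp < 0) nrm = -nrm;
    N(i, 0) = nrm(0); N(i, 1) = nrm(1); N(i, 2) = nrm(2);
    valid[i] = ok;
  }
  return List::create(_["normals"] = N, _["valid"] = valid);
}

static inline void bin_angles(double alpha, double phi, double theta, double* h) {
  // alpha, phi in [-1,1]; theta in [-pi,pi]; 11 bins per feature
  int ia = (int)std::floor((alpha + 1.0) * 0.5 * 11.0);
  int ip = (int)std::floor((phi + 1.0) * 0.5 * 11.0);
  int it = (int)std::floor((theta + M_PI) / (2.0 * M_PI) * 11.0);
  if (ia < 0) ia = 0; if (ia > 10) ia = 10;
  if (ip < 0) ip = 0; if (ip > 10) ip = 10;
  if (it < 0) it = 0; if (it > 10) it = 10;
  h[ia] += 1.0; h[11 + ip] += 1.0; h[22 + it] += 1.0;
}

// Simplified point feature for the pair (source p, target q):
//   u = n_p, d = (q - p)/||q - p||, v = (d x u)/||d x u||, w = u x v
//   alpha = v . n_q, phi = u . d, theta = atan2(w . n_q, u . n_q)
static bool pair_feature(const arma::rowvec& p, const arma::rowvec& np,
                         const arma::rowvec& q, const arma::rowvec& nq,
                         double& alpha, double& phi, double& theta) {
  arma::rowvec d = q - p;
  double len = arma::norm(d);
  if (len < 1e-12) return false;
  d /= len;
  arma::rowvec u = np;
  arma::rowvec v = arma::cross(d, u);
  double vn = arma::norm(v);
  if (vn < 1e-12) return false;  // d parallel to the normal
  v /= vn;
  arma::rowvec w = arma::cross(u, v);
  alpha = arma::dot(v, nq);
  phi = arma::dot(u, d);
  theta = std::atan2(arma::dot(w, nq), arma::dot(u, nq));
  return true;
}

// FPFH(p) = SPFH(p) + (1/k) sum_q SPFH(q)/||p-q||, each 11-bin block then
// normalised to unit mass. Points with no radius neighbours get a zero
// histogram (flagged by the caller through rowSums == 0).
// [[Rcpp::export]]
arma::mat cpp_fpfh(const arma::mat& P, const arma::mat& N, double radius) {
  int n = P.n_rows;
  double r2 = radius * radius;
  std::vector<std::vector<int> > nbr(n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      arma::rowvec d = P.row(j) - P.row(i);
      if (arma::dot(d, d) <= r2) { nbr[i].push_back(j); nbr[j].push_back(i); }
    }
  arma::mat spfh(n, 33, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    double row[33] = {0};
    for (int j : nbr[i]) {
      double a, p2, t;
      if (pair_feature(P.row(i), N.row(i), P.row(j), N.row(j), a, p2, t))
        bin_angles(a, p2, t, row);
    }
    for (int b = 0; b < 33; ++b) spfh(i, b) = row[b];
  }
  arma::mat fpfh(n, 33, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    arma::rowvec acc = spfh.row(i);
    size_t k = nbr[i].size();
    if (k > 0) {
      arma::rowvec wsum(33, arma::fill::zeros);
      for (int j : nbr[i]) {
        double w = arma::norm(P.row(j) - P.row(i));
        if (w > 1e-12) wsum += spfh.row(j) / w;
      }
      acc += wsum / (double)k;
    }
    // normalise each 11-bin block
    for (int b = 0; b < 3; ++b) {
      double s = arma::accu(acc.subvec(11 * b, 11 * b + 10));
      if (s > 0) acc.subvec(11 * b, 11 * b + 10) /= s;
    }
    fpfh.row(i) = acc;
  }
  return fpfh;
}
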