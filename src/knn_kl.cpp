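#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <algorithm>
#include <vector>
using namespace Rcpp;

// kth smallest of squared Euclidean distances from point x to the rows of M,
// optionally excluding row `skip` (pass -1 to keep all rows).
static double kth_dist(const double *x, const NumericMatrix &M, int k,
                       int skip) {
  int n = M.nrow(), d = M.ncol();
  std::vector<double> d2;
  d2.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (i == skip) continue;
    double s = 0.0;
    for (int j = 0; j < d; ++j) {
      double diff = x[j] - M(i, j);
      s += diff * diff;
    }
    d2.push_back(s);
  }
  std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.end());
  return std::sqrt(d2[k - 1]);
}

// k-nearest-neighbour estimator of KL(P||Q) for point clouds
// (Wang, Kulkarni & Verdu 2009):
//   D = (d/n) * sum_i log(nu_k(i) / rho_k(i)) + log(m / (n - 1))
// rho_k: kth NN distance of x_i within P (self excluded);
// nu_k:  kth NN distance of x_i within Q.
// Returned unclamped; callers clamp at zero.
// [[Rcpp::export]]
double kl_knn_cpp(NumericMatrix P, NumericMatrix Q, int k) {
  int n = P.nrow(), m = Q.nrow(), d = P.ncol();
  if (Q.ncol() != d) stop("dimension mismatch between point clouds");
  if (k < 1) stop("k must be positive");
  if (k >= n || k >= m) stop("k must be smaller than both cloud sizes");
  const double eps = 1e-12;
  double acc = 0.0;
  std::vector<double> x(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) x[j] = P(i, j);
    double rho = kth_dist(x.data(), P, k, i);
    double nu = kth_dist(x.data(), Q, k, -1);
    if (rho < eps && nu < eps) continue; // coincident duplicates: no evidence
    if (rho < eps) rho = eps;
    if (nu < eps) nu = eps;
    acc += std::log(nu / rho);
  }
  return ((double)d / n) * acc + std::log((double)m / (double)(n - 1));
}

// kth smallest element of a vector (copy + nth_element), clamped below.
static double kth_of(std::vector<double> &buf, int k) {
  std::nth_element(buf.begin(), buf.begin() + (k - 1), buf.end());
  return buf[k - 1];
}

// Full similarity matrix over a list of standardized vertex clouds:
// s(i,j) = 1 / (1 + max(0, D(i||j)) + max(0, D(j||i))), diagonal 0.
// Self kNN distances are precomputed once per region; each pair needs one
// BLAS cross-distance matrix whose row/column kth minima give both
// divergence directions.
// [[Rcpp::export]]
NumericMatrix mind_matrix_cpp(List clouds, int k) {
  int R = clouds.size();
  NumericMatrix S(R, R);
  const double eps = 1e-12;
  std::vector<arma::mat> cs(R);
  std::vector<arma::vec> sq(R);     // row squared norms
  std::vector<arma::vec> rho(R);    // self kth-NN distance per point
  for (int r = 0; r < R; ++r) {
    cs[r] = as<arma::mat>(clouds[r]);
    int n = cs[r].n_rows;
    if (k >= n) stop("k must be smaller than every cloud size");
    sq[r] = arma::sum(cs[r] % cs[r], 1);
    arma::mat D2 = arma::repmat(sq[r], 1, n) + arma::repmat(sq[r].t(), n, 1) -
                   2.0 * cs[r] * cs[r].t();
    rho[r].set_size(n);
    std::vector<double> buf(n - 1);
    for (int i = 0; i < n; ++i) {
      int c = 0;
      for (int j = 0; j < n; ++j)
        if (j != i) buf[c++] = std::max(D2(j, i), 0.0);
      rho[r](i) = std::sqrt(kth_of(buf, k));
    }
  }
  for (int a = 0; a < R; ++a) {
    int n = cs[a].n_rows;
    for (int b = a + 1; b < R; ++b) {
      int m = cs[b].n_rows;
      arma::mat D2 = arma::repmat(sq[a], 1, m) + arma::repmat(sq[b].t(), n, 1) -
                     2.0 * cs[a] * cs[b].t();
      int d = cs[a].n_cols;
      double acc_ab = 0.0, acc_ba = 0.0;
      std::vector<double> buf(std::max(n, m));
      for (int i = 0; i < n; ++i) { // P = a, Q = b
        buf.resize(m);
        for (int j = 0; j < m; ++j) buf[j] = std::max(D2(i, j), 0.0);
        double nu = std::sqrt(kth_of(buf, k));
        double r0 = rho[a](i);
        if (nu < eps && r0 < eps) continue;
        acc_ab += std::log(std::max(nu, eps) / std::max(r0, eps));
      }
      for (int j = 0; j < m; ++j) { // P = b, Q = a
        buf.resize(n);
        for (int i = 0; i < n; ++i) buf[i] = std::max(D2(i, j), 0.0);
        double nu = std::sqrt(kth_of(buf, k));
        double r0 = rho[b](j);
        if (nu < eps && r0 < eps) continue;
        acc_ba += std::log(std::max(nu, eps) / std::max(r0, eps));
      }
      double dab = ((double)d / n) * acc_ab + std::log((double)m / (n - 1));
      double dba = ((double)d / m) * acc_ba + std::log((double)n / (m - 1));
      double s = 1.0 / (1.0 + std::max(0.0, dab) + std::max(0.0, dba));
      S(a, b) = s;
      S(b, a) = s;
    }
  }
  return S;
}
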