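// Batched REML fits of the longitudinal model used edge-wise:
//   y = X beta + Z_i b_i + e,   b_i ~ N(0, sigma^2 * D),  e ~ N(0, sigma^2 I)
// with Z_i = [1, t] per subject (random intercept + slope of follow-up time).
// D is profiled out relative to sigma^2 and parameterized by its lower
// Cholesky factor L = [[exp(th0), 0], [th1, exp(th2)]]; the residual variance
// is profiled analytically.  All subject-level sufficient statistics are
// precomputed once per response matrix, so one REML objective evaluation is
// O(#subjects) regardless of the number of visits.
#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct SuffStat {
  int n, p, S;
  mat XtX;                 // p x p
  std::vector<double> G;   // per subject: g00, g01, g11 (Z'Z, symmetric)
  std::vector<double> ZtX; // per subject: 2*p values, [row0 | row1]
  // per-edge pieces filled per response:
  std::vector<double> Zty; // per subject: 2 values
  vec Xty;                 // p
  double yty;
};

// REML criterion for one edge given the relative Cholesky factor L
// (D = L L').  Uses C = L (I + L'GL)^-1 L', where I + L'GL is symmetric with
// eigenvalues >= 1, so the inversion is always well-conditioned even when D
// is singular or huge.  Returns criterion and fills beta, covb (unscaled
// (X'V^-1 X)^-1), sigma2.
static double reml_crit(const SuffStat &ss, const mat &L, vec &beta, mat &covb,
                        double &sigma2) {
  int p = ss.p;
  mat XtVX = ss.XtX;
  vec XtVy = ss.Xty;
  double ytVy = ss.yty;
  double logdetV = 0.0;
  const double l00 = L(0, 0), l10 = L(1, 0), l11 = L(1, 1);
  std::vector<double> t0(p), t1(p);
  for (int i = 0; i < ss.S; ++i) {
    const double g00 = ss.G[3 * i], g01 = ss.G[3 * i + 1],
                 g11 = ss.G[3 * i + 2];
    // A = L' G L (2x2, symmetric); M = I + A
    const double gl00 = g00 * l00 + g01 * l10, gl01 = g01 * l11;
    const double gl10 = g01 * l00 + g11 * l10, gl11 = g11 * l11;
    const double m00 = 1.0 + l00 * gl00 + l10 * gl10;
    const double m01 = l00 * gl01 + l10 * gl11;
    const double m11 = 1.0 + l11 * gl11;
    const double det_ = m00 * m11 - m01 * m01;
    if (!(det_ > 1e-300) || !std::isfinite(det_)) return datum::inf;
    logdetV += std::log(det_);
    const double mi00 = m11 / det_, mi01 = -m01 / det_, mi11 = m00 / det_;
    // C = L Minv L' (2x2, symmetric)
    const double lm00 = l00 * mi00, lm01 = l00 * mi01;
    const double lm10 = l10 * mi00 + l11 * mi01,
                 lm11 = l10 * mi01 + l11 * mi11;
    const double c00 = lm00 * l00, c01 = lm00 * l10 + lm01 * l11;
    const double c11 = lm10 * l10 + lm11 * l11;
    const double *zx = &ss.ZtX[2 * p * i];
    const double zy0 = ss.Zty[2 * i], zy1 = ss.Zty[2 * i + 1];
    for (int b = 0; b < p; ++b) {
      t0[b] = c00 * zx[b] + c01 * zx[p + b];
      t1[b] = c01 * zx[b] + c11 * zx[p + b];
    }
    for (int a = 0; a < p; ++a) {
      const double za0 = zx[a], za1 = zx[p + a];
      for (int b = a; b < p; ++b) {
        const double dec = za0 * t0[b] + za1 * t1[b];
        XtVX(a, b) -= dec;
        if (a != b) XtVX(b, a) -= dec;
      }
      XtVy(a) -= za0 * (c00 * zy0 + c01 * zy1) + za1 * (c01 * zy0 + c11 * zy1);
    }
    ytVy -= zy0 * (c00 * zy0 + c01 * zy1) + zy1 * (c01 * zy0 + c11 * zy1);
  }
  mat XtVX_s = symmatu(XtVX);
  double ld2, sign;
  if (!log_det(ld2, sign, XtVX_s) || sign <= 0) return datum::inf;
  vec b;
  if (!solve(b, XtVX_s, XtVy)) return datum::inf;
  double rss = ytVy - dot(b, XtVy);
  if (!(rss > 1e-300)) rss = 1e-300;
  beta = b;
  if (!inv_sympd(covb, XtVX_s)) {
    if (!inv(covb, XtVX_s)) return datum::inf;
  }
  sigma2 = rss / (ss.n - p);
  return logdetV + ld2 + (ss.n - p) * std::log(rss);
}

static mat theta_to_L(const vec &th, bool slope) {
  mat L(2, 2, fill::zeros);
  if (slope) {
    L(0, 0) = std::exp(std::min(th(0), 12.0));
    L(1, 0) = std::max(std::min(th(1), 1e5), -1e5);
    L(1, 1) = std::exp(std::min(th(2), 12.0));
  } else {
    L(0, 0) = std::exp(std::min(th(0), 12.0));
  }
  return L;
}

// Simple Nelder-Mead on the REML criterion.
static vec nelder_mead(const SuffStat &ss, vec start, bool slope, double &best) {
  int k = start.n_elem;
  std::vector<vec> simplex(k + 1);
  std::vector<double> fv(k + 1);
  vec beta;
  mat covb;
  double s2;
  auto f = [&](const vec &th) {
    return reml_crit(ss, theta_to_L(th, slope), beta, covb, s2);
  };
  simplex[0] = start;
  fv[0] = f(start);
  for (int i = 0; i < k; ++i) {
    vec v = start;
    v(i) += 0.5;
    simplex[i + 1] = v;
    fv[i + 1] = f(v);
  }
  int maxit = 400;
  for (int it = 0; it < maxit; ++it) {
    // order
    std::vector<int> ord(k + 1);
    for (int i = 0; i <= k; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return fv[a] < fv[b]; });
    std::vector<vec> sx(k + 1);
    std::vector<double> sf(k + 1);
    for (int i = 0; i <= k; ++i) {
      sx[i] = simplex[ord[i]];
      sf[i] = fv[ord[i]];
    }
    simplex = sx;
    fv = sf;
    if (std::abs(fv[k] - fv[0]) < 1e-9 * (1.0 + std::abs(fv[0]))) break;
    vec cen = zeros<vec>(k);
    for (int i = 0; i < k; ++i) cen += simplex[i];
    cen /= k;
    vec xr = cen + (cen - simplex[k]); // reflect
    double fr = f(xr);
    if (fr < fv[0]) {
      vec xe = cen + 2.0 * (cen - simplex[k]);
      double fe = f(xe);
      if (fe < fr) {
        simplex[k] = xe;
        fv[k] = fe;
      } else {
        simplex[k] = xr;
        fv[k] = fr;
      }
    } else if (fr < fv[k - 1]) {
      simplex[k] = xr;
      fv[k] = fr;
    } else {
      vec xc = cen + 0.5 * (simplex[k] - cen);
      double fc = f(xc);
      if (fc < fv[k]) {
        simplex[k] = xc;
        fv[k] = fc;
      } else { // shrink
        for (int i = 1; i <= k; ++i) {
          simplex[i] = simplex[0] + 0.5 * (simplex[i] - simplex[0]);
          fv[i] = f(simplex[i]);
        }
      }
    }
  }
  int bi = 0;
  for (int i = 1; i <= k; ++i)
    if (fv[i] < fv[bi]) bi = i;
  best = fv[bi];
  return simplex[bi];
}

// [[Rcpp::export]]
Rcpp::List fit_lmm_batch_cpp(const arma::mat &Y, const arma::mat &X,
                             const arma::vec &time,
                             const arma::ivec &subject, int contrast_idx) {
  int n = Y.n_rows, E = Y.n_cols, p = X.n_cols;
  if ((int)X.n_rows != n || (int)time.n_elem != n || (int)subject.n_elem != n)
    Rcpp::stop("row mismatch between Y, X, time and subject");
  int S = subject.max() + 1;
  // group rows by subject
  std::vector<std::vector<int>> rows(S);
  for (int i = 0; i < n; ++i) rows[subject(i)].push_back(i);
  SuffStat ss;
  ss.n = n;
  ss.p = p;
  ss.S = S;
  ss.XtX = X.t() * X;
  ss.G.assign(3 * S, 0.0);
  ss.ZtX.assign(2 * p * S, 0.0);
  ss.Zty.assign(2 * S, 0.0);
  for (int s = 0; s < S; ++s) {
    for (size_t r = 0; r < rows[s].size(); ++r) {
      int row = rows[s][r];
      double t = time(row);
      ss.G[3 * s] += 1.0;
      ss.G[3 * s + 1] += t;
      ss.G[3 * s + 2] += t * t;
      for (int a = 0; a < p; ++a) {
        ss.ZtX[2 * p * s + a] += X(row, a);
        ss.ZtX[2 * p * s + p + a] += t * X(row, a);
      }
    }
  }
  mat B(p, E), covfull;
  vec se(E), tval(E), sigma2(E), sd_int(E), sd_slope(E), re_corr(E);
  Rcpp::IntegerVector flag(E);
  vec beta;
  mat covb;
  double s2;
  for (int e = 0; e < E; ++e) {
    vec y = Y.col(e);
    ss.Xty = X.t() * y;
    ss.yty = dot(y, y);
    std::fill(ss.Zty.begin(), ss.Zty.end(), 0.0);
    for (int s = 0; s < S; ++s) {
      for (size_t r = 0; r < rows[s].size(); ++r) {
        int row = rows[s][r];
        ss.Zty[2 * s] += y(row);
        ss.Zty[2 * s + 1] += time(row) * y(row);
      }
    }
    double best;
    vec th0 = {std::log(0.5), 0.0, std::log(0.5)};
    vec th = nelder_mead(ss, th0, true, best);
    mat Lf = theta_to_L(th, true);
    mat D = Lf * Lf.t();
    double crit = reml_crit(ss, Lf, beta, covb, s2);
    int fl = 0;
    // fall back to random-intercept-only when the slope variance collapses
    // or the full fit failed
    if (!std::isfinite(crit) || D(1, 1) * s2 < 1e-10) {
      vec th1 = {std::log(0.5)};
      vec thb = nelder_mead(ss, th1, false, best);
      mat L1 = theta_to_L(thb, false);
      double crit1 = reml_crit(ss, L1, beta, covb, s2);
      if (std::isfinite(crit1)) {
        D = L1 * L1.t();
        crit = crit1;
        fl = 1;
      }
    }
    if (!std::isfinite(crit)) { // last resort: OLS
      mat XtXi = inv_sympd(symmatu(ss.XtX));
      beta = XtXi * ss.Xty;
      double rss = ss.yty - dot(beta, ss.Xty);
      s2 = rss / (n - p);
      covb = XtXi;
      D = zeros(2, 2);
      fl = 2;
    }
    B.col(e) = beta;
    double v = s2 * covb(contrast_idx, contrast_idx);
    se(e) = std::sqrt(std::max(v, 0.0));
    tval(e) = beta(contrast_idx) / se(e);
    sigma2(e) = s2;
    sd_int(e) = std::sqrt(std::max(D(0, 0) * s2, 0.0));
    sd_slope(e) = std::sqrt(std::max(D(1, 1) * s2, 0.0));
    double den = std::sqrt(D(0, 0) * D(1, 1));
    re_corr(e) = den > 0 ? D(0, 1) / den : NA_REAL;
    flag[e] = fl;
  }
  return Rcpp::List::create(
      Rcpp::Named("beta") = B, Rcpp::Named("se") = se,
      Rcpp::Named("t") = tval, Rcpp::Named("sigma2") = sigma2,
      Rcpp::Named("sd_intercept") = sd_int,
      Rcpp::Named("sd_slope") = sd_slope, Rcpp::Named("re_corr") = re_corr,
      Rcpp::Named("df") = n - p, Rcpp::Named("flag") = flag);
}
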