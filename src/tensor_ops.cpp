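// Per-voxel operations on symmetric 3x3 diffusion tensor fields stored as
// n x 6 matrices with component order (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline arma::mat33 unpack(const NumericMatrix& D6, int v) {
  arma::mat33 M;
  M(0, 0) = D6(v, 0); M(0, 1) = D6(v, 1); M(0, 2) = D6(v, 2);
  M(1, 0) = D6(v, 1); M(1, 1) = D6(v, 3); M(1, 2) = D6(v, 4);
  M(2, 0) = D6(v, 2); M(2, 1) = D6(v, 4); M(2, 2) = D6(v, 5);
  return M;
}

static inline void pack(NumericMatrix& D6, int v, const arma::mat33& M) {
  D6(v, 0) = M(0, 0); D6(v, 1) = M(0, 1); D6(v, 2) = M(0, 2);
  D6(v, 3) = M(1, 1); D6(v, 4) = M(1, 2); D6(v, 5) = M(2, 2);
}

// [[Rcpp::export]]
List clamp_psd_cpp(NumericMatrix D6) {
  const int n = D6.nrow();
  NumericMatrix out(n, 6);
  int n_clamped = 0;
  arma::vec3 eval;
  arma::mat33 evec;
  for (int v = 0; v < n; ++v) {
    bool zero = true;
    for (int k = 0; k < 6; ++k)
      if (D6(v, k) != 0.0) { zero = false; break; }
    if (zero) continue;
    arma::mat33 M = unpack(D6, v);
    arma::eig_sym(eval, evec, M);
    if (eval(0) >= 0.0) {
      pack(out, v, M);
      continue;
    }
    ++n_clamped;
    for (int i = 0; i < 3; ++i)
      if (eval(i) < 0.0) eval(i) = 0.0;
    arma::mat33 R = evec * arma::diagmat(eval) * evec.t();
    pack(out, v, R);
  }
  return List::create(_["components"] = out, _["n_clamped"] = n_clamped);
}

// [[Rcpp::export]]
NumericVector min_eig_field_cpp(NumericMatrix D6) {
  const int n = D6.nrow();
  NumericVector out(n);
  arma::vec3 eval;
  for (int v = 0; v < n; ++v) {
    arma::mat33 M = unpack(D6, v);
    arma::eig_sym(eval, M);
    out[v] = eval(0);
  }
  return out;
}

// Builds the tumor-cell diffusion tensor field: in white matter the water
// tensor's eigenvalue profile is sharpened with anisotropy factor a >= 1 via
// the Westin shape measures and rescaled so that trace(D) = 3 * dwhite; in
// gray matter D = gray_ratio * dwhite * I; elsewhere D = 0.
// labels: 0 background, 1 CSF, 2 gray, 3 white.
// [[Rcpp::export]]
List build_tumor_tensor_cpp(NumericMatrix water6, IntegerVector labels,
                            double a, double gray_ratio, double dwhite) {
  const int n = water6.nrow();
  NumericMatrix out(n, 6);
  std::vector<int> bad;
  arma::vec3 eval;
  arma::mat33 evec;
  const double dgray = gray_ratio * dwhite;
  for (int v = 0; v < n; ++v) {
    const int lab = labels[v];
    if (lab == 2) {
      out(v, 0) = dgray; out(v, 3) = dgray; out(v, 5) = dgray;
      continue;
    }
    if (lab != 3) continue;
    arma::mat33 M = unpack(water6, v);
    arma::eig_sym(eval, evec, M);   // ascending
    const double l1 = eval(2), l2 = eval(1), l3 = eval(0);
    const double s = l1 + l2 + l3;
    if (s <= 0.0) {
      bad.push_back(v + 1);
      continue;
    }
    const double cl = (l1 - l2) / s;
    const double cp = 2.0 * (l2 - l3) / s;
    const double cs = 3.0 * l3 / s;
    // l-vector: rows (a, a, 1), (1, a, 1), (1, 1, 1) acting on (cl, cp, cs)
    const double w1 = a * cl + a * cp + cs;
    const double w2 = cl + a * cp + cs;
    const double w3 = cl + cp + cs;   // = 1 identically
    const double lt1 = w1 * l1, lt2 = w2 * l2, lt3 = w3 * l3;
    const double st = lt1 + lt2 + lt3;
    arma::mat33 R = (3.0 * dwhite / st) *
      (lt1 * evec.col(2) * evec.col(2).t() +
       lt2 * evec.col(1) * evec.col(1).t() +
       lt3 * evec.col(0) * evec.col(0).t());
    pack(out, v, R);
  }
  return List::create(_["components"] = out,
                      _["bad_white_voxels"] = wrap(bad));
}
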