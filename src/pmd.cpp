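#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Elementwise soft-thresholding operator S(v, lam)_i = sign(v_i) max(|v_i| - lam, 0).
static vec soft(const vec &v, double lam) {
  return sign(v) % clamp(abs(v) - lam, 0.0, datum::inf);
}

// Unit-L2 vector proportional to S(a, lam) with the smallest lam >= 0 such that
// its L1 norm is <= c.  Feasible whenever c >= 1 (unit L2 implies L1 >= 1).
static vec l1_unit(const vec &a, double c) {
  const double nrm = norm(a, 2);
  if (nrm <= 0) return zeros<vec>(a.n_elem);
  vec w = a / nrm;
  if (norm(w, 1) <= c + 1e-12) return w;
  double lo = 0.0, hi = abs(a).max();
  for (int it = 0; it < 40; ++it) {
    double mid = 0.5 * (lo + hi);
    vec s = soft(a, mid);
    double n2 = norm(s, 2);
    if (n2 <= 0) { hi = mid; continue; }
    if (norm(s / n2, 1) > c) lo = mid; else hi = mid;
  }
  vec s = soft(a, hi);
  double n2 = norm(s, 2);
  if (n2 <= 0) { // fall back to the single largest entry
    vec w1 = zeros<vec>(a.n_elem);
    uword i = index_max(abs(a));
    w1(i) = a(i) >= 0 ? 1.0 : -1.0;
    return w1;
  }
  return s / n2;
}

// [[Rcpp::export(name = ".l1_unit_cpp")]]
arma::vec l1_unit_cpp(const arma::vec &a, double c) { return l1_unit(a, c); }

// Rank-1 penalized matrix decomposition of a cross-covariance matrix C (p x q):
// alternating L1-bounded unit-norm updates, initialized from (wx0, wy0).
static void pmd_core(const mat &C, double cx, double cy, double tol, int max_iter,
                     vec &wx, vec &wy, double &d, int &iters, bool &converged) {
  converged = false;
  iters = 0;
  for (int it = 1; it <= max_iter; ++it) {
    iters = it;
    vec wx_new = l1_unit(C * wy, cx);
    vec wy_new = l1_unit(C.t() * wx_new, cy);
    double delta = std::max(abs(wx_new - wx).max(), abs(wy_new - wy).max());
    wx = wx_new;
    wy = wy_new;
    if (delta < tol) { converged = true; break; }
  }
  d = as_scalar(wx.t() * C * wy);
  if (d < 0) { wy = -wy; d = -d; } // sign convention: covariance of the pair >= 0
}

// Deterministic initialization: leading singular vectors of C.
static void svd_init(const mat &C, vec &wx0, vec &wy0) {
  mat U, V;
  vec s;
  svd_econ(U, s, V, C);
  wx0 = U.col(0);
  wy0 = V.col(0);
}

// [[Rcpp::export(name = ".pmd_rank1_cpp")]]
Rcpp::List pmd_rank1_cpp(const arma::mat &C, double cx, double cy,
                         double tol, int max_iter,
                         Rcpp::Nullable<Rcpp::NumericVector> init_x = R_NilValue,
                         Rcpp::Nullable<Rcpp::NumericVector> init_y = R_NilValue) {
  vec wx0, wy0;
  if (init_x.isNotNull() && init_y.isNotNull()) {
    wx0 = Rcpp::as<vec>(init_x.get());
    wy0 = Rcpp::as<vec>(init_y.get());
  } else {
    svd_init(C, wx0, wy0);
  }
  vec wx = wx0, wy = wy0;
  double d;
  int iters;
  bool conv;
  pmd_core(C, cx, cy, tol, max_iter, wx, wy, d, iters, conv);
  return Rcpp::List::create(Rcpp::Named("wx") = wx, Rcpp::Named("wy") = wy,
                            Rcpp::Named("d") = d, Rcpp::Named("iterations") = iters,
                            Rcpp::Named("converged") = conv);
}

// Non-zero selection frequencies over half-sample resamples.  `idx` holds
// 0-based participant row indices, one resample per column.
// [[Rcpp::export(name = ".stability_freq_cpp")]]
Rcpp::List stability_freq_cpp(const arma::mat &X, const arma::mat &Y,
                              const arma::umat &idx, double cx, double cy,
                              double tol, int max_iter) {
  const uword p = X.n_cols, q = Y.n_cols, R = idx.n_cols;
  vec freq_x = zeros<vec>(p), freq_y = zeros<vec>(q);
  const double m = static_cast<double>(idx.n_rows);
  for (uword r = 0; r < R; ++r) {
    uvec rows = idx.col(r);
    mat Xs = X.rows(rows), Ys = Y.rows(rows);
    mat C = Xs.t() * Ys / (m - 1.0);
    vec wx, wy;
    svd_init(C, wx, wy);
    double d;
    int iters;
    bool conv;
    pmd_core(C, cx, cy, tol, max_iter, wx, wy, d, iters, conv);
    freq_x += conv_to<vec>::from(abs(wx) > 1e-8);
    freq_y += conv_to<vec>::from(abs(wy) > 1e-8);
  }
  freq_x /= static_cast<double>(R);
  freq_y /= static_cast<double>(R);
  return Rcpp::List::create(Rcpp::Named("freq_x") = freq_x,
                            Rcpp::Named("freq_y") = freq_y);
}
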