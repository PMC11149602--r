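// Non-negative least squares (Lawson-Hanson active set, normal-equation
// form) and the batched voxel fitter used for kinetic mapping.  Problems are
// tiny (K basis elements, K <= ~12) but numerous: every voxel is solved at
// every candidate delay, so the loop lives in C++.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Solve min_{x >= 0} x'AtA x - 2 Atb'x.  tol is an absolute gradient
// tolerance on the normal equations.
static vec nnls_normal(const mat& AtA, const vec& Atb, double tol) {
  const uword K = Atb.n_elem;
  std::vector<bool> passive(K, false);
  vec x(K, fill::zeros);
  vec grad = Atb;                       // Atb - AtA x at x = 0
  uword outer = 0, max_outer = 3 * K + 30;

  while (outer++ < max_outer) {
    // most violated KKT coordinate among the active (zero) set
    int t = -1;
    double gmax = tol;
    for (uword k = 0; k < K; ++k)
      if (!passive[k] && grad(k) > gmax) { gmax = grad(k); t = (int)k; }
    if (t < 0) break;
    passive[t] = true;

    uword inner = 0, max_inner = 10 * K + 50;
    while (inner++ < max_inner) {
      std::vector<uword> pidx;
      for (uword k = 0; k < K; ++k) if (passive[k]) pidx.push_back(k);
      uvec idx(pidx);

      vec s;
      bool ok = solve(s, AtA.submat(idx, idx), Atb(idx),
                      solve_opts::likely_sympd + solve_opts::no_approx);
      if (!ok) s = pinv(AtA.submat(idx, idx)) * Atb(idx);

      if (s.min() > 0) {
        x.zeros();
        x(idx) = s;
        break;
      }
      // step toward s until the first passive coordinate hits zero
      double step = datum::inf;
      for (uword m = 0; m < idx.n_elem; ++m)
        if (s(m) <= 0) {
          double d = x(idx(m)) / (x(idx(m)) - s(m));
          if (d < step) step = d;
        }
      if (!std::isfinite(step)) step = 0;
      for (uword m = 0; m < idx.n_elem; ++m)
        x(idx(m)) += step * (s(m) - x(idx(m)));
      double floor_tol = 1e-12 * (1.0 + x.max());
      for (uword k = 0; k < K; ++k)
        if (passive[k] && x(k) <= floor_tol) { passive[k] = false; x(k) = 0; }
    }
    grad = Atb - AtA * x;
  }
  return x;
}

// [[Rcpp::export]]
arma::vec nnls_solve_cpp(const arma::mat& AtA, const arma::vec& Atb,
                         double tol = 1e-10) {
  double scale = std::max(1.0, arma::abs(Atb).max());
  return nnls_normal(AtA, Atb, tol * scale);
}

// Batched weighted NNLS fit of TAC columns over a delay grid.
// Z: J x N data; M: J x (K*D) matrix of basis tissue curves, delay-major
// (columns 1..K are delay 1, etc.); w: J frame weights; tol as above.
// Returns alpha (K x N), delta index (1-based), wrss (N), fitted (J x N,
// only when want_fitted).
// [[Rcpp::export]]
Rcpp::List fit_tacs_cpp(const arma::mat& Z, const arma::mat& M,
                        int K, int D, const arma::vec& w,
                        double tol = 1e-10, bool want_fitted = false) {
  const uword J = Z.n_rows, N = Z.n_cols;
  if (M.n_rows != J || (int)M.n_cols != K * D)
    Rcpp::stop("basis matrix dimensions do not match");

  // precompute per-delay weighted normal matrices
  std::vector<mat> AtA(D);
  std::vector<mat> AtW(D);  // K x J, equals M_d' diag(w)
  for (int d = 0; d < D; ++d) {
    mat Md = M.cols(d * K, d * K + K - 1);
    mat MdW = Md.each_col() % w;       // J x K
    AtA[d] = Md.t() * MdW;
    AtW[d] = MdW.t();
  }

  mat alpha(K, N, fill::zeros);
  ivec best_d(N, fill::ones);
  vec wrss(N, fill::zeros);
  mat fitted;
  if (want_fitted) fitted.zeros(J, N);

  for (uword i = 0; i < N; ++i) {
    vec z = Z.col(i);
    double zWz = dot(w % z, z);
    double best = datum::inf;
    vec best_x(K, fill::zeros);
    int bd = 0;
    for (int d = 0; d < D; ++d) {
      vec Atb = AtW[d] * z;
      double scale = std::max(1.0, arma::abs(Atb).max());
      vec x = nnls_normal(AtA[d], Atb, tol * scale);
      double r = zWz - 2.0 * dot(x, Atb) + as_scalar(x.t() * AtA[d] * x);
      if (r < 0) r = 0;
      if (!std::isfinite(best) || r < best - 1e-15 * (1 + std::abs(best))) {
        best = r; best_x = x; bd = d;
      }
    }
    alpha.col(i) = best_x;
    best_d(i) = bd + 1;
    wrss(i) = best;
    if (want_fitted)
      fitted.col(i) = M.cols(bd * K, bd * K + K - 1) * best_x;
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("alpha") = alpha,
      Rcpp::Named("delta_index") = best_d,
      Rcpp::Named("wrss") = wrss);
  if (want_fitted) out["fitted"] = fitted;
  return out;
}
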