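// Lawson-Hanson active-set solver for min ||A x - b||^2 s.t. x >= 0.
// Compiled because the curve estimator calls it thousands of times per
// data set (once per (b1, b2) grid candidate). Supports warm-starting the
// passive set, which makes sweeps over nearby (b1, b2) candidates cheap:
// the optimal support changes little between adjacent grid points.
//
// Least-squares subproblems use a Cholesky fast path on the normal
// equations (the Gram matrix is formed once per call) with a QR fallback
// on the original columns when the Gram submatrix is numerically rank
// deficient; KKT optimality is always checked on the final iterate.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// LS fit restricted to columns p, via Gram fast path then QR fallback
static vec ls_on(const mat& A, const mat& G, const vec& Atb,
                 const uvec& p, const vec& b) {
  vec s;
  bool ok = solve(s, G.submat(p, p), Atb(p),
                  solve_opts::likely_sympd + solve_opts::no_approx);
  if (!ok || !s.is_finite()) {
    ok = solve(s, A.cols(p), b, solve_opts::allow_ugly);
    if (!ok || !s.is_finite()) s = pinv(A.cols(p)) * b;
  }
  return s;
}

// [[Rcpp::export]]
Rcpp::List nnls_lh(const arma::mat& A0, const arma::vec& b,
                   double tol = -1.0, int max_iter = -1,
                   Rcpp::Nullable<Rcpp::IntegerVector> warm = R_NilValue) {
  const uword n = A0.n_cols;
  if (A0.n_rows != b.n_elem)
    Rcpp::stop("dimension mismatch between A and b");

  // column normalisation makes the optimality test scale invariant
  // (columns of exponential-kernel design matrices can differ by many
  // orders of magnitude); the solution is unscaled on exit
  vec cnorm(n);
  mat A = A0;
  for (uword k = 0; k < n; ++k) {
    double s = norm(A.col(k), 2);
    cnorm(k) = (s > 0.0) ? s : 1.0;
    A.col(k) /= cnorm(k);
  }

  if (tol <= 0.0)
    tol = 10.0 * datum::eps * norm(A, 1) * std::max(A.n_rows, A.n_cols);
  if (max_iter <= 0)
    max_iter = 10 * static_cast<int>(n) + 50;

  const mat G = A.t() * A;
  const vec Atb = A.t() * b;

  vec x(n, fill::zeros);
  std::vector<bool> passive(n, false);
  int outer = 0;

  auto passive_idx = [&]() {
    uvec p(n);
    uword np = 0;
    for (uword k = 0; k < n; ++k) if (passive[k]) p(np++) = k;
    p.resize(np);
    return p;
  };

  // restore primal feasibility of the unconstrained fit on the current
  // passive set, shrinking the set until the fit is non-negative
  auto inner_loop = [&]() {
    for (;;) {
      uvec p = passive_idx();
      if (p.n_elem == 0) { x.zeros(); return; }
      vec s = ls_on(A, G, Atb, p, b);
      if (s.min() > 0) {
        x.zeros();
        x(p) = s;
        return;
      }
      double alpha = datum::inf;
      for (uword k = 0; k < p.n_elem; ++k)
        if (s(k) <= 0) {
          double a = x(p(k)) / (x(p(k)) - s(k));
          if (a < alpha) alpha = a;
        }
      if (!std::isfinite(alpha)) alpha = 0.0;
      vec xp = x(p) + alpha * (s - x(p));
      x.zeros();
      x(p) = xp;
      for (uword k = 0; k < p.n_elem; ++k)
        if (s(k) <= 0 && xp(k) <= 1e-12 * (1.0 + std::abs(s(k)))) {
          passive[p(k)] = false;
          x(p(k)) = 0.0;
        }
    }
  };

  if (warm.isNotNull()) {
    Rcpp::IntegerVector w0(warm);
    for (int k = 0; k < w0.size(); ++k) {
      int j = w0[k];
      if (j >= 0 && j < static_cast<int>(n)) passive[j] = true;
    }
    inner_loop();
  }

  vec w = Atb - G * x;
  while (outer < max_iter) {
    double wmax = tol;
    sword j = -1;
    for (uword k = 0; k < n; ++k)
      if (!passive[k] && w(k) > wmax) { wmax = w(k); j = k; }
    if (j < 0) break;             // KKT conditions satisfied
    passive[j] = true;
    ++outer;
    inner_loop();
    w = Atb - G * x;
  }

  vec resid = b - A * x;
  x /= cnorm;                     // undo the column scaling
  uvec p = passive_idx();
  return Rcpp::List::create(
      Rcpp::Named("x") = x,
      Rcpp::Named("rss") = dot(resid, resid),
      Rcpp::Named("iterations") = outer,
      Rcpp::Named("passive") = Rcpp::IntegerVector(p.begin(), p.end()));
}
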