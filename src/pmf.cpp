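// Weighted positive matrix factorisation by alternating non-negative least
// squares.  The model is X ~ G F with G (n x k) >= 0 and F (k x m) >= 0,
// fitted by minimising the uncertainty-scaled objective
//   Q = sum_ij ((x_ij - sum_k g_ik f_kj) / u_ij)^2 .
// Each sweep solves every row of G and every column-block of F exactly via
// the normal-equation form of Lawson-Hanson NNLS (k is small, typically
// 3-7), so Q is non-increasing by construction.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// NNLS on the normal equations: minimise x' ZtZ x - 2 Ztb' x  s.t. x >= 0.
// Lawson-Hanson active-set; ZtZ is k x k symmetric positive (semi)definite.
static vec nnls_normal(const mat& ZtZ, const vec& Ztb, const int max_outer = 200) {
  const uword k = Ztb.n_elem;
  vec x = zeros<vec>(k);
  uvec passive = zeros<uvec>(k);  // 1 = in passive (free) set
  vec w = Ztb;                    // negative gradient at x = 0
  const double tol = 1e-12 * (1.0 + norm(Ztb, "inf"));

  for (int outer = 0; outer < max_outer; ++outer) {
    // most violating coordinate among the active set
    int t = -1;
    double wmax = tol;
    for (uword j = 0; j < k; ++j) {
      if (!passive(j) && w(j) > wmax) { wmax = w(j); t = (int)j; }
    }
    if (t < 0) break;
    passive(t) = 1;

    for (int inner = 0; inner < max_outer; ++inner) {
      uvec P = find(passive == 1);
      vec z = zeros<vec>(k);
      mat A = ZtZ.submat(P, P);
      vec b = Ztb.elem(P);
      vec zP;
      if (!solve(zP, A, b, solve_opts::likely_sympd + solve_opts::no_approx)) {
        zP = pinv(A) * b;
      }
      z.elem(P) = zP;
      if (zP.min() > 0) { x = z; break; }
      // step toward z until the first passive coordinate hits zero
      double alpha = datum::inf;
      for (uword idx = 0; idx < P.n_elem; ++idx) {
        uword j = P(idx);
        if (z(j) <= 0) {
          double a = x(j) / (x(j) - z(j));
          if (a < alpha) alpha = a;
        }
      }
      x += alpha * (z - x);
      for (uword j = 0; j < k; ++j) {
        if (passive(j) && x(j) <= tol) { x(j) = 0; passive(j) = 0; }
      }
    }
    w = Ztb - ZtZ * x;
  }
  return x;
}

static double q_objective(const mat& X, const mat& W, const mat& G, const mat& F) {
  mat R = (X - G * F);
  return accu(W % square(R));
}

// [[Rcpp::export(name = ".pmf_als")]]
Rcpp::List pmf_als(const arma::mat& X, const arma::mat& U,
                   arma::mat G, arma::mat F,
                   const int max_iter, const double tol) {
  const uword n = X.n_rows, m = X.n_cols, k = G.n_cols;
  mat W = 1.0 / square(U);  // per-cell weights

  std::vector<double> qtrace;
  double q_prev = q_objective(X, W, G, F);
  qtrace.push_back(q_prev);
  bool converged = false;
  // absolute floor: an exact fit keeps shrinking Q geometrically, so the
  // relative criterion alone would never fire; scale by sum((X/u)^2)
  const double q_floor = 1e-16 * accu(W % square(X));

  for (int it = 0; it < max_iter; ++it) {
    // rows of G: min over g >= 0 of sum_j w_ij (x_ij - g' f_.j)^2
    for (uword i = 0; i < n; ++i) {
      mat Fw = F.each_row() % W.row(i);          // k x m
      mat ZtZ = Fw * F.t();                      // k x k
      vec Ztb = Fw * X.row(i).t();               // k
      G.row(i) = nnls_normal(ZtZ, Ztb).t();
    }
    // columns of F: min over f >= 0 of sum_i w_ij (x_ij - g_i.' f)^2
    for (uword j = 0; j < m; ++j) {
      mat Gw = G.each_col() % W.col(j);          // n x k
      mat ZtZ = Gw.t() * G;                      // k x k
      vec Ztb = Gw.t() * X.col(j);               // k
      F.col(j) = nnls_normal(ZtZ, Ztb);
    }
    double q = q_objective(X, W, G, F);
    qtrace.push_back(q);
    double denom = (q_prev > 0) ? q_prev : 1.0;
    if (q <= q_floor || std::abs(q_prev - q) / denom < tol) {
      converged = true; q_prev = q; break;
    }
    q_prev = q;
  }

  (void)k; (void)m;
  return Rcpp::List::create(
    Rcpp::Named("G") = G,
    Rcpp::Named("F") = F,
    Rcpp::Named("Q") = q_prev,
    Rcpp::Named("q_trace") = qtrace,
    Rcpp::Named("converged") = converged);
}
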