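#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lawson-Hanson active-set non-negative least squares:
//   minimise ||A x - b||_2 subject to x >= 0.
// The design matrices here are small (n_frames x n_basis), but the solver
// is called once per voxel, so it lives in C++.
static vec nnls_one(const mat& A, const vec& b, double tol, int max_iter) {
  const uword p = A.n_cols;
  vec x(p, fill::zeros);
  uvec passive(p, fill::zeros);  // 1 = in passive (free) set
  vec w = A.t() * (b - A * x);

  int iter = 0;
  while (true) {
    // find most violated constraint among active variables
    double wmax = -datum::inf;
    sword t = -1;
    for (uword j = 0; j < p; ++j) {
      if (!passive(j) && w(j) > wmax) { wmax = w(j); t = j; }
    }
    if (t < 0 || wmax <= tol) break;
    passive(t) = 1;

    while (true) {
      if (++iter > max_iter) return x;
      uvec P = find(passive == 1);
      vec z(p, fill::zeros);
      vec zP;
      if (!solve(zP, A.cols(P), b)) return x;
      z(P) = zP;
      if (zP.min() > tol) { x = z; break; }
      // step toward z until the first passive variable hits zero
      double alpha = datum::inf;
      for (uword k = 0; k < P.n_elem; ++k) {
        uword j = P(k);
        if (z(j) <= tol) {
          double a = x(j) / (x(j) - z(j));
          if (a < alpha) alpha = a;
        }
      }
      x += alpha * (z - x);
      for (uword j = 0; j < p; ++j) {
        if (passive(j) && x(j) <= tol) { passive(j) = 0; x(j) = 0; }
      }
    }
    w = A.t() * (b - A * x);
  }
  return x;
}

// [[Rcpp::export]]
Rcpp::NumericVector nnls_solve(const arma::mat& A, const arma::vec& b,
                               double tol = 1e-10, int max_iter = 1000) {
  vec x = nnls_one(A, b, tol, max_iter);
  return Rcpp::NumericVector(x.begin(), x.end());
}

// Solve NNLS for every column of B against the shared design A.
// Returns coefficients (p x ncol(B)) and residual sums of squares.
// [[Rcpp::export]]
Rcpp::List nnls_solve_many(const arma::mat& A, const arma::mat& B,
                           double tol = 1e-10, int max_iter = 1000) {
  const uword m = B.n_cols;
  mat X(A.n_cols, m);
  vec rss(m);
  for (uword i = 0; i < m; ++i) {
    vec x = nnls_one(A, B.col(i), tol, max_iter);
    X.col(i) = x;
    rss(i) = accu(square(B.col(i) - A * x));
  }
  return Rcpp::List::create(Rcpp::Named("coef") = X,
                            Rcpp::Named("rss") = rss);
}
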