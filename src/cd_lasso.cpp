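#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the lasso in covariance form.
//
// Objective: (1/2n) * ||y - X b||^2 + lambda * sum_j pf[j] * |b[j]|
// parameterized by G = X'X / n and c = X'y / n, so each full sweep is
// O(p^2) regardless of n. X and y are assumed centered by the caller
// (intercept recovered there). pf[j] = 0 marks an unpenalized column.
//
// Returns a p x nlambda coefficient matrix; the lambda grid must be
// decreasing so warm starts carry the active set down the path.

static inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// [[Rcpp::export]]
NumericMatrix cd_lasso_path_cpp(const NumericMatrix& G,
                                const NumericVector& c,
                                const NumericVector& lambda,
                                const NumericVector& pf,
                                double tol,
                                int maxit) {
  const int p = G.nrow();
  const int nlam = lambda.size();
  NumericMatrix beta(p, nlam);
  std::vector<double> b(p, 0.0);

  for (int l = 0; l < nlam; ++l) {
    const double lam = lambda[l];
    int it = 0;
    for (; it < maxit; ++it) {
      double max_delta = 0.0;
      for (int j = 0; j < p; ++j) {
        const double gjj = G(j, j);
        if (gjj <= 0.0) { b[j] = 0.0; continue; }
        // partial residual correlation: c_j - sum_{k != j} G_jk b_k
        double r = c[j];
        for (int k = 0; k < p; ++k) {
          if (k != j && b[k] != 0.0) r -= G(j, k) * b[k];
        }
        const double bj_new = soft_threshold(r, lam * pf[j]) / gjj;
        const double d = bj_new - b[j];
        if (d != 0.0) {
          const double scaled = std::sqrt(gjj) * std::fabs(d);
          if (scaled > max_delta) max_delta = scaled;
          b[j] = bj_new;
        }
      }
      if (max_delta < tol) break;
    }
    if (it == maxit) {
      stop("coordinate descent did not converge at lambda = %f "
           "(maxit = %d, tol = %g)", lam, maxit, tol);
    }
    for (int j = 0; j < p; ++j) beta(j, l) = b[j];
  }
  return beta;
}
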