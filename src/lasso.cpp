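#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the lasso objective
//   (1/(2n)) * ||y - X b||^2 + lambda * ||b||_1
// on a column-centered X and centered y (intercept handled by the caller).
// Lambdas must be supplied in decreasing order; solutions are warm-started
// along the path. Active-set cycling: after each full sweep, only the
// currently nonzero coordinates are iterated until they stabilize, then a
// full sweep checks for violators. Convergence: max absolute coefficient
// change < tol over a clean full sweep.
//
// [[Rcpp::export]]
NumericMatrix lasso_path_cd(const NumericMatrix& X, const NumericVector& y,
                            const NumericVector& lambdas,
                            double tol = 1e-10, int max_iter = 100000) {
  const int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  NumericMatrix beta(p, L);
  std::vector<double> b(p, 0.0), r(y.begin(), y.end());
  std::vector<double> xx(p); // colSums(X^2)/n
  std::vector<int> active;
  active.reserve(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    const double* xj = &X(0, j);
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xx[j] = s / n;
  }
  auto update = [&](int j, double lam) -> double {
    const double* xj = &X(0, j);
    double rho = 0.0;
    for (int i = 0; i < n; ++i) rho += xj[i] * r[i];
    rho = rho / n + xx[j] * b[j];
    double bn = 0.0;
    if (rho > lam) bn = (rho - lam) / xx[j];
    else if (rho < -lam) bn = (rho + lam) / xx[j];
    const double d = b[j] - bn;
    if (d != 0.0) {
      for (int i = 0; i < n; ++i) r[i] += xj[i] * d;
      b[j] = bn;
    }
    return d < 0 ? -d : d;
  };
  for (int l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    int iter = 0;
    while (iter < max_iter) {
      // full sweep
      double max_delta = 0.0;
      for (int j = 0; j < p; ++j) {
        if (xx[j] <= 0.0) continue;
        const double d = update(j, lam);
        if (d > max_delta) max_delta = d;
      }
      ++iter;
      if (max_delta < tol) break;
      // converge on the active set
      active.clear();
      for (int j = 0; j < p; ++j)
        if (b[j] != 0.0 && xx[j] > 0.0) active.push_back(j);
      while (iter < max_iter) {
        double md = 0.0;
        for (int j : active) {
          const double d = update(j, lam);
          if (d > md) md = d;
        }
        ++iter;
        if (md < tol) break;
      }
    }
    for (int j = 0; j < p; ++j) beta(j, l) = b[j];
  }
  return beta;
}
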