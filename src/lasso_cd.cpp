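#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the penalized least-squares objective
//   ||X v - Y||_2^2 + beta ||v||_1
// in its literal scaling (no 1/(2n) factor). Columns are visited in fixed
// order, so the solve is deterministic. `betas` is a (typically decreasing)
// penalty grid; solutions are warm-started along it. Returns a p x G matrix
// of coefficients, one column per grid point.
// [[Rcpp::export]]
NumericMatrix cd_lasso_path(const NumericMatrix& X, const NumericVector& Y,
                            const NumericVector& betas, double tol, int maxit,
                            const NumericVector& v0) {
  const int n = X.nrow(), p = X.ncol(), G = betas.size();
  NumericMatrix V(p, G);
  std::vector<double> v(p, 0.0);
  if (v0.size() == p) for (int j = 0; j < p; ++j) v[j] = v0[j];
  // residual r = Y - X v for the warm start
  std::vector<double> r(Y.begin(), Y.end());
  for (int j = 0; j < p; ++j) {
    if (v[j] != 0.0) for (int i = 0; i < n; ++i) r[i] -= X(i, j) * v[j];
  }
  std::vector<double> d(p);  // column squared norms X_j' X_j
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    d[j] = s;
  }
  double gammaCur = 0.0;
  const double* xp = REAL(X);
  std::vector<int> active;
  active.reserve(p);
  // one coordinate update; returns |change|
  auto update = [&](int j) -> double {
    double rho = v[j] * d[j];
    const double* xj = xp + (std::size_t)j * n;
    for (int i = 0; i < n; ++i) rho += xj[i] * r[i];
    const double a = std::fabs(rho) - gammaCur;
    const double vnew = (a > 0.0) ? ((rho > 0.0 ? a : -a) / d[j]) : 0.0;
    const double ch = vnew - v[j];
    if (ch != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= xj[i] * ch;
      v[j] = vnew;
    }
    return std::fabs(ch);
  };
  for (int g = 0; g < G; ++g) {
    gammaCur = betas[g] / 2.0;  // soft-threshold level of this objective
    int it = 0;
    for (;;) {
      // full sweep over every coordinate (fixed order), collecting the
      // active set
      double delta = 0.0;
      active.clear();
      for (int j = 0; j < p; ++j) {
        if (d[j] <= 0.0) continue;  // empty column stays at zero
        const double ach = update(j);
        if (ach > delta) delta = ach;
        if (v[j] != 0.0) active.push_back(j);
      }
      if (++it > maxit)
        stop("coordinate descent did not converge (max coefficient change %g after %d sweeps)",
             delta, maxit);
      if (delta <= tol) break;
      // iterate the active set to convergence before the next full sweep
      for (;;) {
        double da = 0.0;
        for (int j : active) {
          const double ach = update(j);
          if (ach > da) da = ach;
        }
        if (++it > maxit)
          stop("coordinate descent did not converge (max coefficient change %g after %d sweeps)",
               da, maxit);
        if (da <= tol) break;
      }
    }
    for (int j = 0; j < p; ++j) V(j, g) = v[j];
  }
  return V;
}
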