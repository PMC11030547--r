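#include <Rcpp.h>
using namespace Rcpp;

static inline double soft(double a, double b) {
  if (a > b) return a - b;
  if (a < -b) return a + b;
  return 0.0;
}

// Cyclic coordinate descent for the elastic net
//   min over (b0, beta):
//     (1/(2n)) sum_i (y_i - b0 - x_i.beta)^2
//     + lambda * (alpha * sum_j |beta_j| + (1-alpha)/2 * sum_j beta_j^2)
// Soft-threshold update beta_j <- S(rho_j, lambda*alpha) / (z_j + lambda*(1-alpha))
// with rho_j = (1/n) sum_i x_ij (r_i + x_ij beta_j), z_j = (1/n) sum_i x_ij^2;
// the intercept absorbs the mean residual each sweep. Columns are NOT
// standardized internally. Warm starts: lambdas are visited in the order
// given and (b0, beta) carry over.
//
// Returns, per lambda: coefficients, intercept, sweep count, convergence
// flag (max coefficient change < tol), and the last max change.
// [[Rcpp::export]]
List elnet_path_cpp(NumericMatrix X, NumericVector y, double alpha,
                    NumericVector lambdas, double tol, int max_iter,
                    double b0_init, NumericVector beta_init) {
  const int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  std::vector<double> z(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    const double* xj = &X(0, j);
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    z[j] = s / n;
  }
  std::vector<double> beta(p);
  for (int j = 0; j < p; ++j) beta[j] = beta_init[j];
  double b0 = b0_init;
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) {
    double fit = b0;
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) fit += X(i, j) * beta[j];
    r[i] = y[i] - fit;
  }

  NumericMatrix B(p, L);
  NumericVector B0(L), maxdelta(L);
  IntegerVector sweeps(L);
  LogicalVector converged(L);

  std::vector<char> active(p, 0);

  for (int l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    const double thr = lam * alpha;
    const double denom_add = lam * (1.0 - alpha);
    double dmax = R_PosInf;
    int it = 0;
    // active-set strategy: full sweeps establish the working set; inner
    // sweeps iterate over it until stable; a final full sweep must then
    // pass without changing the set (and below tol) to declare convergence.
    bool full_pass = true;
    while (it < max_iter) {
      ++it;
      dmax = 0.0;
      bool set_changed = false;
      double mr = 0.0;
      for (int i = 0; i < n; ++i) mr += r[i];
      mr /= n;
      if (mr != 0.0) {
        b0 += mr;
        for (int i = 0; i < n; ++i) r[i] -= mr;
      }
      if (std::abs(mr) > dmax) dmax = std::abs(mr);
      for (int j = 0; j < p; ++j) {
        if (!full_pass && !active[j]) continue;
        if (z[j] <= 0.0) { beta[j] = 0.0; continue; }
        const double* xj = &X(0, j);
        double dot = 0.0;
        for (int i = 0; i < n; ++i) dot += xj[i] * r[i];
        const double rho = dot / n + z[j] * beta[j];
        const double bn = soft(rho, thr) / (z[j] + denom_add);
        const double d = bn - beta[j];
        if (d != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
          beta[j] = bn;
          if (std::abs(d) > dmax) dmax = std::abs(d);
        }
        const char now_active = (beta[j] != 0.0);
        if (full_pass && now_active && !active[j]) { active[j] = 1; set_changed = true; }
        else active[j] = now_active;
      }
      if (dmax < tol) {
        if (full_pass && !set_changed) break;   // converged on a full sweep
        full_pass = true;                        // verify with a full sweep
      } else {
        full_pass = false;                       // keep iterating the active set
      }
    }
    for (int j = 0; j < p; ++j) B(j, l) = beta[j];
    B0[l] = b0;
    sweeps[l] = it;
    converged[l] = (dmax < tol);
    maxdelta[l] = dmax;
  }
  return List::create(_["beta"] = B, _["b0"] = B0, _["sweeps"] = sweeps,
                      _["converged"] = converged, _["max_delta"] = maxdelta);
}

// Objective value after each of `nsweeps` coordinate-descent sweeps at a
// single lambda, from a cold start. Used to verify objective descent.
// [[Rcpp::export]]
NumericVector elnet_sweep_objectives_cpp(NumericMatrix X, NumericVector y,
                                         double alpha, double lambda,
                                         int nsweeps) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> z(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    z[j] = s / n;
  }
  std::vector<double> beta(p, 0.0), r(y.begin(), y.end());
  NumericVector obj(nsweeps);
  const double thr = lambda * alpha, denom_add = lambda * (1.0 - alpha);
  for (int s = 0; s < nsweeps; ++s) {
    double mr = 0.0;
    for (int i = 0; i < n; ++i) mr += r[i];
    mr /= n;
    for (int i = 0; i < n; ++i) r[i] -= mr;   // intercept absorbs the mean
    for (int j = 0; j < p; ++j) {
      if (z[j] <= 0.0) continue;
      double dot = 0.0;
      for (int i = 0; i < n; ++i) dot += X(i, j) * r[i];
      const double rho = dot / n + z[j] * beta[j];
      const double bn = soft(rho, thr) / (z[j] + denom_add);
      const double d = bn - beta[j];
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= X(i, j) * d;
        beta[j] = bn;
      }
    }
    double rss = 0.0, l1 = 0.0, l2 = 0.0;
    for (int i = 0; i < n; ++i) rss += r[i] * r[i];
    for (int j = 0; j < p; ++j) { l1 += std::abs(beta[j]); l2 += beta[j] * beta[j]; }
    obj[s] = rss / (2.0 * n) + lambda * (alpha * l1 + 0.5 * (1.0 - alpha) * l2);
  }
  return obj;
}
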