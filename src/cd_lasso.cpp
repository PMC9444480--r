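// Cyclic coordinate descent for the penalized sparse-coding problem
//   min_a ||x - D a||_2^2 + lambda * ||a||_1
// (no 1/2 factor on the quadratic term; the scalar update is therefore
// a_k = soft(rho_k, lambda / 2) / ||d_k||^2 with rho_k the partial residual
// correlation). Gram and correlation matrices are precomputed once per
// batch, so each coordinate update is O(K) and only when the coefficient
// actually moves. Periodically, and at apparent convergence, the current
// active set's stationarity system is solved exactly ("polishing", as in
// standard lasso solvers); the polished iterate is accepted only when it is
// sign-consistent and lowers the objective. This also rescues the
// ill-conditioned lambda = 0 case, where plain coordinate descent crawls.

#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// [[Rcpp::export(name = ".cd_lasso_cpp")]]
List cd_lasso_cpp(const arma::mat& D, const arma::mat& X, double lambda,
                  double tol, int max_iter, bool trace) {
  const arma::uword K = D.n_cols, n = X.n_cols;
  arma::mat G = D.t() * D;              // K x K Gram
  arma::vec g = G.diag();               // atom squared norms
  // correlations are computed column-by-column so that a batch solve is
  // bitwise identical to independent single-signal solves
  arma::mat C(K, n);
  arma::vec xsq(n);
  for (arma::uword j = 0; j < n; ++j) {
    C.col(j) = D.t() * X.col(j);
    xsq(j) = arma::dot(X.col(j), X.col(j));
  }

  arma::mat A(K, n, arma::fill::zeros); // codes
  arma::ivec iters(n, arma::fill::zeros);
  arma::ivec conv(n, arma::fill::zeros);
  List traces(trace ? n : 0);
  const double thr = lambda / 2.0;

  for (arma::uword j = 0; j < n; ++j) {
    arma::vec a(K, arma::fill::zeros);
    arma::vec Ga(K, arma::fill::zeros); // G * a, maintained incrementally
    std::vector<double> objs;

    auto objective = [&](const arma::vec& v, const arma::vec& Gv) {
      return xsq(j) - 2.0 * arma::dot(v, C.col(j)) + arma::dot(v, Gv) +
             lambda * arma::norm(v, 1);
    };

    // exact solve of the stationarity system on a candidate support;
    // accepted only when sign-consistent and objective-decreasing
    auto try_support = [&](const arma::uvec& act) -> double {
      arma::mat As = G.submat(act, act);
      arma::vec s = arma::sign(a.elem(act));
      arma::vec cj = C.col(j);
      arma::vec b = cj.elem(act) - thr * s;
      arma::vec sol;
      if (!arma::solve(sol, As, b, arma::solve_opts::likely_sympd))
        return 0.0;
      if (lambda > 0.0) {
        for (arma::uword t = 0; t < sol.n_elem; ++t)
          if (sol(t) * s(t) < 0.0) return 0.0;   // sign flip: reject
      }
      arma::vec anew(K, arma::fill::zeros);
      anew.elem(act) = sol;
      arma::vec Ganew = G * anew;
      if (objective(anew, Ganew) >= objective(a, Ga) - 1e-15) return 0.0;
      double delta = arma::abs(anew - a).max();
      a = anew;
      Ga = Ganew;
      return delta;
    };

    // polish the current active set; on degenerate (singular or
    // sign-inconsistent) supports retry with the weakest atoms dropped
    auto polish = [&]() -> double {
      arma::uvec act = arma::find(a != 0.0);
      for (int attempt = 0; attempt < 4 && !act.is_empty(); ++attempt) {
        double d = try_support(act);
        if (d > 0.0) return d;
        arma::vec mags = arma::abs(a.elem(act));
        act.shed_row(mags.index_min());
      }
      return 0.0;
    };

    int it = 0;
    for (; it < max_iter; ++it) {
      double max_delta = 0.0;
      for (arma::uword k = 0; k < K; ++k) {
        if (g(k) <= 0.0) { a(k) = 0.0; continue; } // zero-norm atom
        double rho = C(k, j) - Ga(k) + g(k) * a(k);
        double anew = soft(rho, thr) / g(k);
        double delta = anew - a(k);
        if (delta != 0.0) {
          a(k) = anew;
          Ga += G.col(k) * delta;
          double ad = std::abs(delta);
          if (ad > max_delta) max_delta = ad;
        }
      }
      bool settled = max_delta < tol;
      if (settled || (it + 1) % 10 == 0) {
        double pd = polish();
        if (pd > max_delta) max_delta = pd;
        settled = max_delta < tol;
      }
      if (trace) objs.push_back(objective(a, Ga));
      if (settled) { conv(j) = 1; ++it; break; }
    }
    iters(j) = it;
    A.col(j) = a;
    if (trace) traces[j] = NumericVector(objs.begin(), objs.end());
  }

  return List::create(_["coef"] = A, _["iters"] = iters,
                      _["converged"] = conv, _["objective_trace"] = traces);
}
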