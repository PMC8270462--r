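// Inner solvers for the alternating minimization:
//  - per-sample non-negative least squares (active set on the Gram system)
//  - non-negative LASSO coordinate descent for the signature subproblem
// Loss convention: squared Frobenius norm without a 1/2 factor, so the
// stationarity threshold for a coefficient is lambda/2 and the maximal
// penalty is 2 * max positive entry of alpha' * R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// min ||A x - b||^2, x >= 0, given G = A'A and c = A'b (Lawson-Hanson).
static vec nnls_gram(const mat& G, const vec& c) {
  const uword p = G.n_cols;
  vec x(p, fill::zeros);
  std::vector<bool> passive(p, false);
  const double tol = 1e-12 * std::max(1.0, std::abs(c.max())) ;
  vec w = c;  // -(1/2) gradient at x = 0
  uword outer = 0, max_outer = 10 * p + 30;

  while (outer++ < max_outer) {
    // most violating free coordinate
    int t = -1;
    double wmax = tol;
    for (uword k = 0; k < p; ++k) {
      if (!passive[k] && w[k] > wmax) { wmax = w[k]; t = (int)k; }
    }
    if (t < 0) break;
    passive[t] = true;

    uword inner = 0, max_inner = 10 * p + 30;
    while (inner++ < max_inner) {
      uvec idx(p);
      uword np = 0;
      for (uword k = 0; k < p; ++k) if (passive[k]) idx[np++] = k;
      idx.resize(np);
      vec z;
      bool ok = solve(z, G.submat(idx, idx), c.elem(idx),
                      solve_opts::likely_sympd + solve_opts::no_approx);
      if (!ok) z = pinv(G.submat(idx, idx)) * c.elem(idx);
      if (np == 0) break;
      if (z.min() > 0) {
        x.zeros();
        x.elem(idx) = z;
        break;
      }
      // back-track to the boundary, drop one variable
      double step = datum::inf;
      int drop = -1;
      for (uword j = 0; j < np; ++j) {
        if (z[j] <= 0) {
          double xi = x[idx[j]];
          double a = xi / (xi - z[j]);
          if (a < step) { step = a; drop = (int)idx[j]; }
        }
      }
      for (uword j = 0; j < np; ++j) {
        x[idx[j]] += step * (z[j] - x[idx[j]]);
        if (x[idx[j]] < 0) x[idx[j]] = 0;
      }
      if (drop >= 0) { x[drop] = 0; passive[drop] = false; }
    }
    w = c - G * x;
  }
  return x;
}

// Exposures for all samples: rows of M are fitted against the signature
// basis B (p x 96, background row included by the caller).
// [[Rcpp::export]]
arma::mat cpp_update_exposures(const arma::mat& M, const arma::mat& B) {
  const uword n = M.n_rows, p = B.n_rows;
  mat G = B * B.t();
  mat A(n, p, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    vec c = B * M.row(i).t();
    A.row(i) = nnls_gram(G, c).t();
  }
  return A;
}

// Signature subproblem: min ||R - alpha beta||_F^2 + lambda ||beta||_1,
// beta >= 0, by cyclic coordinate descent over the K x 96 entries.
// G = alpha'alpha (K x K), C = alpha'R (K x 96). Columns are independent
// given G. Converges when the relative change of the penalized objective
// (offset by r2 = ||R||_F^2) drops below tol.
// [[Rcpp::export]]
Rcpp::List cpp_nnlasso(const arma::mat& G, const arma::mat& C,
                       const arma::mat& Binit, double lambda, double r2,
                       double tol, int max_sweeps) {
  const uword K = G.n_rows, J = C.n_cols;
  mat B = Binit;
  vec g = G.diag();
  const double half_lambda = lambda / 2.0;
  const double geps = 1e-12 * std::max(1.0, g.max());

  auto objective = [&](const mat& Bm) {
    return r2 - 2.0 * accu(C % Bm) + accu((G * Bm) % Bm) +
           lambda * accu(Bm);
  };

  double f_prev = objective(B);
  // the objective is computed as a difference of large quantities, so a
  // near-exact fit leaves it dominated by cancellation noise of order
  // eps * r2; treat changes below that floor as converged
  const double noise_floor = 64.0 * datum::eps * (r2 + 1.0);
  int sweep = 0;
  bool converged = false;
  for (sweep = 1; sweep <= max_sweeps; ++sweep) {
    double max_delta = 0.0, max_b = 0.0;
    for (uword j = 0; j < J; ++j) {
      for (uword k = 0; k < K; ++k) {
        if (g[k] <= geps) {
          // signature with no exposure: unidentifiable, shrink if penalized
          if (lambda > 0) B(k, j) = 0;
          continue;
        }
        double r = C(k, j) - dot(G.row(k), B.col(j)) + g[k] * B(k, j);
        double b = (r - half_lambda) / g[k];
        if (b < 0) b = 0.0;
        double d = std::abs(b - B(k, j));
        if (d > max_delta) max_delta = d;
        if (b > max_b) max_b = b;
        B(k, j) = b;
      }
    }
    double f = objective(B);
    double denom = std::max(1.0, std::abs(f_prev));
    if (std::abs(f_prev - f) <= std::max(tol * denom, noise_floor) ||
        max_delta <= 1e-12 * std::max(1.0, max_b)) {
      converged = true; f_prev = f; break;
    }
    f_prev = f;
  }
  return Rcpp::List::create(Rcpp::Named("beta") = B,
                            Rcpp::Named("sweeps") = sweep,
                            Rcpp::Named("converged") = converged,
                            Rcpp::Named("objective") = f_prev);
}
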