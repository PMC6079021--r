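#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// L1-penalised inverse covariance (graphical lasso) by block coordinate
// descent over the columns of the covariance estimate W (Friedman, Hastie &
// Tibshirani 2008).  Each column update solves a lasso problem by
// coordinate descent with an explicitly maintained residual vector r = W
// beta, so a coordinate visit is O(1) and only an accepted update costs
// O(p).  The penalty applies to off-diagonal entries only (W keeps
// diag(S) + rho on its diagonal).  S must be symmetric and positive
// definite; the caller is responsible for ridge regularisation.
//
// Returns the precision estimate Theta, the covariance estimate W, the
// sweep count, and a convergence flag.
// [[Rcpp::export]]
Rcpp::List cpp_glasso(const arma::mat& S, double rho, double tol,
                      int maxit, int inner_maxit) {
  const uword p = S.n_rows;
  mat W = S;
  W.diag() = S.diag() + rho;
  mat B(p, p, fill::zeros); // column j holds beta for block j

  // convergence scale: mean absolute off-diagonal of S
  double offsum = accu(abs(S)) - accu(abs(S.diag()));
  double scale = (p > 1) ? offsum / (double)(p * (p - 1)) : 1.0;
  if (scale <= 0) scale = 1.0;
  const double thr = tol * scale;
  const double ithr = 0.1 * thr;

  int it = 0;
  bool converged = false;
  vec r(p);

  for (it = 1; it <= maxit; ++it) {
    double dmax_w = 0.0;
    for (uword j = 0; j < p; ++j) {
      vec beta = B.col(j);
      beta(j) = 0.0;
      // r = W * beta over the current support (W changed since last sweep)
      r.zeros();
      for (uword l = 0; l < p; ++l)
        if (beta(l) != 0.0) r += beta(l) * W.col(l);

      // one full coordinate pass, then refinement over the active set only
      // (the next outer sweep revisits every coordinate anyway)
      auto visit = [&](uword k) -> double {
        const double vkk = W(k, k);
        const double z = S(k, j) - r(k) + vkk * beta(k);
        double bnew = 0.0;
        if (z > rho) bnew = (z - rho) / vkk;
        else if (z < -rho) bnew = (z + rho) / vkk;
        const double d = bnew - beta(k);
        if (d != 0.0) {
          r += d * W.col(k);
          beta(k) = bnew;
        }
        return std::fabs(d);
      };
      double dmax = 0.0;
      for (uword k = 0; k < p; ++k)
        if (k != j) dmax = std::max(dmax, visit(k));
      if (dmax >= ithr) {
        std::vector<uword> active;
        active.reserve(64);
        for (uword k = 0; k < p; ++k)
          if (k != j && beta(k) != 0.0) active.push_back(k);
        for (int pass = 1; pass < inner_maxit; ++pass) {
          dmax = 0.0;
          for (uword k : active) dmax = std::max(dmax, visit(k));
          if (dmax < ithr) break;
        }
      }

      // w12 = W11 beta  (r already equals W * beta with beta(j) = 0)
      for (uword k = 0; k < p; ++k) {
        if (k == j) continue;
        const double d = std::fabs(r(k) - W(k, j));
        if (d > dmax_w) dmax_w = d;
        W(k, j) = r(k);
        W(j, k) = r(k);
      }
      B.col(j) = beta;
    }
    if (dmax_w < thr) { converged = true; break; }
  }

  // recover Theta from W and the regression coefficients
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    double q = W(j, j);
    for (uword k = 0; k < p; ++k)
      if (k != j) q -= W(k, j) * B(k, j);
    const double tjj = 1.0 / q;
    Theta(j, j) = tjj;
    for (uword k = 0; k < p; ++k)
      if (k != j) Theta(k, j) = -B(k, j) * tjj;
  }
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(Rcpp::Named("theta") = Theta,
                            Rcpp::Named("w") = W,
                            Rcpp::Named("niter") = it,
                            Rcpp::Named("converged") = converged);
}

// Blockwise sum of absolute values: collapses a (b*L) x (b*L) matrix into
// an L x L matrix of per-block L1 norms.  Used for the coupling score
// PS_ij = sum_ab |theta_ij^ab| over the 20 x 20 block linking columns i, j.
// [[Rcpp::export]]
arma::mat cpp_block_abs_sum(const arma::mat& M, int block) {
  const uword b = (uword)block;
  const uword L = M.n_rows / b;
  mat out(L, L, fill::zeros);
  for (uword i = 0; i < L; ++i)
    for (uword j = 0; j < L; ++j)
      out(i, j) = accu(abs(M.submat(i * b, j * b, (i + 1) * b - 1,
                                    (j + 1) * b - 1)));
  return out;
}
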