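#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Elementwise soft-threshold: sign(v) * max(|v| - gamma, 0)
static inline vec soft(const vec& v, double gamma) {
  return sign(v) % clamp(abs(v) - gamma, 0.0, datum::inf);
}

// Proximal-gradient (ISTA) solver for the naive elastic net
//   (1/n) ||y - X beta||^2 + tau ||beta||_1 + mu ||beta||_2^2
// Step constant C must satisfy C >= 2 * (sigma_max(X'X)/n + mu) so the
// gradient step is non-expansive; stops when the max-norm coefficient
// change falls below tol.
static void ista_run(const mat& X, const vec& y, double tau, double mu,
                     double C, double tol, uword max_iter,
                     vec& beta, uword& iters, bool& converged) {
  const double n = static_cast<double>(X.n_rows);
  const double thr = tau / C;
  converged = false;
  iters = 0;
  for (uword it = 1; it <= max_iter; ++it) {
    vec grad = (2.0 / n) * (X.t() * (X * beta - y)) + 2.0 * mu * beta;
    vec beta_new = soft(beta - grad / C, thr);
    double delta = beta_new.is_empty() ? 0.0 : abs(beta_new - beta).max();
    beta = beta_new;
    iters = it;
    if (delta < tol) { converged = true; break; }
  }
}

// Largest singular value of X'X (= sigma_max(X)^2), via SVD.
static double xtx_spectral_norm(const mat& X) {
  vec s = svd(X);
  return s.is_empty() ? 0.0 : s(0) * s(0);
}

// [[Rcpp::export(name = ".enet_ista_cpp")]]
Rcpp::List enet_ista_cpp(const arma::mat& X, const arma::vec& y,
                         double tau, double mu, arma::vec beta0,
                         double tol, int max_iter) {
  const double n = static_cast<double>(X.n_rows);
  const double C = 2.0 * (xtx_spectral_norm(X) / n + mu) + 1e-12;
  vec beta = beta0;
  uword iters; bool converged;
  ista_run(X, y, tau, mu, C, tol, static_cast<uword>(max_iter),
           beta, iters, converged);
  return Rcpp::List::create(
    Rcpp::Named("beta") = beta,
    Rcpp::Named("iterations") = static_cast<int>(iters),
    Rcpp::Named("converged") = converged,
    Rcpp::Named("step_constant") = C);
}

// Warm-started path over a decreasing tau sequence at fixed mu; column j of
// the returned matrix is the solution at taus[j].
// [[Rcpp::export(name = ".enet_path_cpp")]]
Rcpp::List enet_path_cpp(const arma::mat& X, const arma::vec& y,
                         const arma::vec& taus, double mu,
                         double tol, int max_iter) {
  const double n = static_cast<double>(X.n_rows);
  const double C = 2.0 * (xtx_spectral_norm(X) / n + mu) + 1e-12;
  mat betas(X.n_cols, taus.n_elem, fill::zeros);
  Rcpp::IntegerVector iters(taus.n_elem);
  Rcpp::LogicalVector conv(taus.n_elem);
  vec beta(X.n_cols, fill::zeros);
  for (uword j = 0; j < taus.n_elem; ++j) {
    uword it; bool ok;
    ista_run(X, y, taus(j), mu, C, tol, static_cast<uword>(max_iter),
             beta, it, ok);
    betas.col(j) = beta;
    iters[j] = static_cast<int>(it);
    conv[j] = ok;
  }
  return Rcpp::List::create(
    Rcpp::Named("betas") = betas,
    Rcpp::Named("iterations") = iters,
    Rcpp::Named("converged") = conv,
    Rcpp::Named("step_constant") = C);
}
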