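// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Weighted multinomial logistic regression by Newton-Raphson (IRLS), used for
// the local logistic step of ABC scenario choice.  Class K is the reference;
// coefficients are a p x (K-1) matrix.  The first column of X is expected to
// be the intercept: the ridge penalizes the slope coefficients only, which
// keeps the Hessian invertible under quasi-separation and tempers local
// overfitting without biasing the fitted class odds at the evaluation point.
// Returns the coefficient matrix, the observed-information covariance of
// vec(coef), and the weighted log-likelihood.
// [[Rcpp::export(name = ".multinom_irls_cpp")]]
List multinom_irls_cpp(arma::mat X, arma::ivec y, arma::vec w, int K,
                       double ridge = 1e-6, int maxit = 50, double tol = 1e-8) {
  const int n = X.n_rows, p = X.n_cols, Km = K - 1;
  arma::mat B(p, Km, arma::fill::zeros);
  arma::mat Y(n, Km, arma::fill::zeros);
  for (int i = 0; i < n; ++i)
    if (y[i] >= 1 && y[i] <= Km) Y(i, y[i] - 1) = 1.0;

  auto loglik = [&](const arma::mat& B) {
    arma::mat eta = X * B;
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double mx = 0.0;
      for (int k = 0; k < Km; ++k) mx = std::max(mx, eta(i, k));
      double denom = std::exp(-mx);
      for (int k = 0; k < Km; ++k) denom += std::exp(eta(i, k) - mx);
      const double lse = mx + std::log(denom);
      const double et = (y[i] >= 1 && y[i] <= Km) ? eta(i, y[i] - 1) : 0.0;
      ll += w[i] * (et - lse);
    }
    ll -= 0.5 * ridge * (arma::accu(B % B) - arma::accu(B.row(0) % B.row(0)));
    return ll;
  };

  double ll = loglik(B);
  arma::mat P(n, Km);
  arma::mat H(p * Km, p * Km);
  arma::vec g(p * Km);
  bool converged = false;

  for (int it = 0; it < maxit; ++it) {
    arma::mat eta = X * B;
    for (int i = 0; i < n; ++i) {
      double mx = 0.0;
      for (int k = 0; k < Km; ++k) mx = std::max(mx, eta(i, k));
      double denom = std::exp(-mx);
      for (int k = 0; k < Km; ++k) denom += std::exp(eta(i, k) - mx);
      for (int k = 0; k < Km; ++k) P(i, k) = std::exp(eta(i, k) - mx) / denom;
    }
    // gradient and Hessian blocks
    for (int k = 0; k < Km; ++k) {
      arma::vec rk = w % (Y.col(k) - P.col(k));
      arma::vec pen = ridge * B.col(k);
      pen[0] = 0.0;
      g.subvec(k * p, (k + 1) * p - 1) = X.t() * rk - pen;
    }
    for (int k = 0; k < Km; ++k)
      for (int m = k; m < Km; ++m) {
        arma::vec wk;
        if (k == m) wk = w % P.col(k) % (1.0 - P.col(k));
        else wk = -(w % P.col(k) % P.col(m));
        arma::mat blk = X.t() * (X.each_col() % wk);
        if (k == m) { blk.diag() += ridge; blk(0, 0) -= ridge; }
        H.submat(k * p, m * p, (k + 1) * p - 1, (m + 1) * p - 1) = blk;
        if (k != m)
          H.submat(m * p, k * p, (m + 1) * p - 1, (k + 1) * p - 1) = blk.t();
      }
    arma::vec step;
    if (!arma::solve(step, H, g, arma::solve_opts::likely_sympd)) {
      H.diag() += 1e-4;
      if (!arma::solve(step, H, g)) break;
    }
    // step-halving line search
    double t = 1.0, llnew = ll;
    arma::mat Bnew = B;
    for (int h = 0; h < 20; ++h) {
      Bnew = B;
      for (int k = 0; k < Km; ++k)
        Bnew.col(k) += t * step.subvec(k * p, (k + 1) * p - 1);
      llnew = loglik(Bnew);
      if (llnew >= ll - 1e-12) break;
      t *= 0.5;
    }
    const double delta = llnew - ll;
    B = Bnew; ll = llnew;
    if (std::fabs(delta) < tol * (std::fabs(ll) + 1.0)) { converged = true; break; }
  }
  arma::mat vcov;
  if (!arma::inv_sympd(vcov, H)) {
    H.diag() += 1e-6;
    if (!arma::inv(vcov, H)) vcov = arma::mat(p * (K - 1), p * (K - 1), arma::fill::value(NA_REAL));
  }
  return List::create(_["coef"] = B, _["vcov"] = vcov,
                      _["loglik"] = ll, _["converged"] = converged);
}
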