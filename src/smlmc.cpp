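// Core numerics for the SM-LMC multi-output GP: marginal log likelihood and
// analytic gradients with respect to every kernel hyperparameter class.
// Called thousands of times per fit; the block Gram assembly and the
// trace-form gradient contractions are the hot path.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Cholesky with escalating relative jitter. Returns true on success and
// fills R_out (upper triangular) and jitter_used.
static bool chol_jitter_cpp(const arma::mat& K, arma::mat& R_out,
                            double& jitter_used) {
  if (arma::chol(R_out, K)) { jitter_used = 0.0; return true; }
  double md = arma::mean(K.diag());
  for (double jit = 1e-8; jit <= 1e-2 * 1.0000001; jit *= 10.0) {
    arma::mat Kj = K;
    Kj.diag() += jit * md;
    if (arma::chol(R_out, Kj)) { jitter_used = jit; return true; }
  }
  return false;
}

// [[Rcpp::export(name = ".smlmc_ll_grad")]]
List smlmc_ll_grad(const arma::vec& x, const arma::vec& y,
                   const arma::uvec& d1,           // 1-based covariate index
                   const arma::vec& mu, const arma::vec& v,
                   const List& A_list, const arma::mat& lambda, // D x Q
                   const arma::vec& s2, int D, bool want_grad) {
  const arma::uword T = x.n_elem;
  const arma::uword Q = mu.n_elem;
  arma::uvec d0 = d1 - 1;

  arma::mat rho(T, T);
  for (arma::uword i = 0; i < T; ++i)
    for (arma::uword j = 0; j < T; ++j)
      rho(i, j) = std::fabs(x[i] - x[j]);
  arma::mat rho2 = rho % rho;

  std::vector<arma::mat> Kq(Q), Eq(Q), Bfull(Q);
  arma::mat K(T, T, arma::fill::zeros);
  const double twopi2 = 2.0 * M_PI * M_PI;
  for (arma::uword q = 0; q < Q; ++q) {
    arma::mat Aq = as<arma::mat>(A_list[q]);
    arma::mat Bq = Aq * Aq.t();
    Bq.diag() += lambda.col(q);
    Eq[q] = arma::exp(-twopi2 * v[q] * rho2);
    if (mu[q] > 0.0)
      Kq[q] = Eq[q] % arma::cos(2.0 * M_PI * mu[q] * rho);
    else
      Kq[q] = Eq[q];
    Bfull[q] = Bq.submat(d0, d0);
    K += Bfull[q] % Kq[q];
  }
  for (arma::uword t = 0; t < T; ++t) K(t, t) += s2[d0[t]];

  arma::mat R;
  double jit;
  if (!chol_jitter_cpp(K, R, jit)) {
    return List::create(_["ok"] = false);
  }
  arma::vec alpha = arma::solve(arma::trimatu(R),
                                arma::solve(arma::trimatl(R.t()), y));
  double logdet = 2.0 * arma::accu(arma::log(R.diag()));
  double ll = -0.5 * arma::dot(y, alpha) - 0.5 * logdet -
    0.5 * double(T) * std::log(2.0 * M_PI);

  if (!want_grad) {
    return List::create(_["ok"] = true, _["ll"] = ll, _["jitter"] = jit);
  }

  arma::mat Rinv = arma::inv(arma::trimatu(R));
  arma::mat Kinv = Rinv * Rinv.t();
  arma::mat M = 0.5 * (alpha * alpha.t() - Kinv);

  // covariate indicator (T x D) for the block contractions
  arma::mat P(T, D, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t) P(t, d0[t]) = 1.0;

  arma::vec dmu(Q, arma::fill::zeros), dv(Q, arma::fill::zeros);
  arma::mat dlam(D, Q, arma::fill::zeros);
  List dA(Q);
  for (arma::uword q = 0; q < Q; ++q) {
    arma::mat Wq = M % Kq[q];
    arma::mat Gq = P.t() * Wq * P;
    arma::mat Aq = as<arma::mat>(A_list[q]);
    dA[q] = arma::mat((Gq + Gq.t()) * Aq);
    dlam.col(q) = Gq.diag();
    dv[q] = -twopi2 * arma::accu(Wq % Bfull[q] % rho2);
    if (mu[q] > 0.0) {
      arma::mat Sq = arma::sin(2.0 * M_PI * mu[q] * rho);
      dmu[q] = -2.0 * M_PI *
        arma::accu(M % Bfull[q] % Eq[q] % rho % Sq);
    }
  }
  arma::vec ds2(D, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t) ds2[d0[t]] += M(t, t);

  return List::create(_["ok"] = true, _["ll"] = ll, _["jitter"] = jit,
                      _["dmu"] = dmu, _["dv"] = dv, _["dA"] = dA,
                      _["dlam"] = dlam, _["ds2"] = ds2);
}
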