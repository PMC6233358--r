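// Core recursions for the random-walk (constant-level) state-space model
//   eta_k = theta_k + v_k,            v_k ~ N(0, V)
//   theta_k = theta_{k-1} + w_k,      w_k ~ N(0, g_k * W)
//   theta_0 ~ N(m0, c0 * I)
// with integer gap g_k >= 0 between consecutive sample indices: g_k > 1
// marginalizes fully missing base-interval steps, g_k = 0 encodes technical
// replicates (no evolution).  Provides the marginal log likelihood
// p(eta | V, W) and its analytic gradients with respect to eta (smoothing
// identity) and to V and W (Fisher's identity with smoothed moments).
// Numerical failures (overflowed or non-PD covariances, as arise on extreme
// MCMC proposals) yield loglik = -Inf rather than an exception.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static bool chol_lower(mat& L, const mat& S) {
  if (!S.is_finite()) return false;
  return chol(L, symmatu(S), "lower");
}

static bool inv_spd(mat& out, const mat& S) {
  if (!S.is_finite()) return false;
  return inv_sympd(out, symmatu(S));
}

static double log_mvn_chol(const vec& x, const vec& m, const mat& L) {
  vec z = solve(trimatl(L), x - m);
  return -0.5 * (double)x.n_elem * std::log(2.0 * M_PI)
         - accu(log(L.diag())) - 0.5 * dot(z, z);
}

// [[Rcpp::export(name = ".dlm_rw_loglik_cpp")]]
double dlm_rw_loglik_cpp(const arma::mat& eta, const arma::vec& gaps,
                         const arma::vec& m0, double c0,
                         const arma::mat& V, const arma::mat& W) {
  const uword p = eta.n_rows, K = eta.n_cols;
  vec m = m0;
  mat C = c0 * eye(p, p);
  double ll = 0.0;
  mat L, Qi;
  for (uword k = 0; k < K; ++k) {
    mat R = symmatu(C + gaps(k) * W);
    mat Q = symmatu(R + V);
    if (!chol_lower(L, Q) || !inv_spd(Qi, Q)) return R_NegInf;
    ll += log_mvn_chol(eta.col(k), m, L);
    mat Kg = R * Qi;
    m += Kg * (eta.col(k) - m);
    C = symmatu(R - Kg * R);
  }
  return ll;
}

// [[Rcpp::export(name = ".dlm_rw_lp_grad_cpp")]]
Rcpp::List dlm_rw_lp_grad_cpp(const arma::mat& eta, const arma::vec& gaps,
                              const arma::vec& m0, double c0,
                              const arma::mat& V, const arma::mat& W) {
  const uword p = eta.n_rows, K = eta.n_cols;
  Rcpp::List fail = Rcpp::List::create(
      Rcpp::Named("loglik") = R_NegInf,
      Rcpp::Named("grad_eta") = mat(p, K, fill::zeros),
      Rcpp::Named("score_V") = mat(p, p, fill::zeros),
      Rcpp::Named("score_W") = mat(p, p, fill::zeros),
      Rcpp::Named("smoothed_mean") = mat(p, K + 1, fill::zeros),
      Rcpp::Named("smoothed_cov") = cube(p, p, K + 1, fill::zeros));
  mat Vi;
  if (!inv_spd(Vi, V)) return fail;
  bool any_gap = any(gaps > 0);
  mat Wi;
  if (any_gap && !inv_spd(Wi, W)) return fail;

  // forward filter, storing moments
  cube Cf(p, p, K + 1), Rs(p, p, K + 1);
  mat mf(p, K + 1);
  mf.col(0) = m0;
  Cf.slice(0) = c0 * eye(p, p);
  Rs.slice(0).zeros();  // unused
  double ll = 0.0;
  mat L, Qi;
  for (uword k = 1; k <= K; ++k) {
    mat R = symmatu(Cf.slice(k - 1) + gaps(k - 1) * W);
    mat Q = symmatu(R + V);
    if (!chol_lower(L, Q) || !inv_spd(Qi, Q)) return fail;
    ll += log_mvn_chol(eta.col(k - 1), mf.col(k - 1), L);
    mat Kg = R * Qi;
    mf.col(k) = mf.col(k - 1) + Kg * (eta.col(k - 1) - mf.col(k - 1));
    Cf.slice(k) = symmatu(R - Kg * R);
    Rs.slice(k) = R;
  }

  // RTS smoother with lag-one covariances
  cube Ss(p, p, K + 1), lag1(p, p, K);  // lag1.slice(k) = Cov(th_k, th_{k+1})
  mat sm(p, K + 1);
  sm.col(K) = mf.col(K);
  Ss.slice(K) = Cf.slice(K);
  mat Ri;
  for (uword k = K; k-- > 0;) {
    if (!inv_spd(Ri, Rs.slice(k + 1))) return fail;
    mat J = Cf.slice(k) * Ri;
    sm.col(k) = mf.col(k) + J * (sm.col(k + 1) - mf.col(k));
    Ss.slice(k) = symmatu(Cf.slice(k) +
                          J * (Ss.slice(k + 1) - Rs.slice(k + 1)) * J.t());
    lag1.slice(k) = J * Ss.slice(k + 1);
  }

  // gradients
  mat grad_eta(p, K);
  mat score_V(p, p, fill::zeros), score_W(p, p, fill::zeros);
  for (uword k = 1; k <= K; ++k) {
    vec d = eta.col(k - 1) - sm.col(k);
    grad_eta.col(k - 1) = -Vi * d;
    mat D = d * d.t() + Ss.slice(k);
    score_V += 0.5 * (Vi * D * Vi - Vi);
    double g = gaps(k - 1);
    if (g > 0) {
      vec dd = sm.col(k) - sm.col(k - 1);
      mat E = Ss.slice(k) + Ss.slice(k - 1) - lag1.slice(k - 1)
              - lag1.slice(k - 1).t() + dd * dd.t();
      score_W += 0.5 * ((1.0 / g) * Wi * E * Wi - Wi);
    }
  }
  if (!std::isfinite(ll) || !grad_eta.is_finite() ||
      !score_V.is_finite() || !score_W.is_finite()) return fail;

  return Rcpp::List::create(
      Rcpp::Named("loglik") = ll,
      Rcpp::Named("grad_eta") = grad_eta,
      Rcpp::Named("score_V") = symmatu(score_V),
      Rcpp::Named("score_W") = symmatu(score_W),
      Rcpp::Named("smoothed_mean") = sm,
      Rcpp::Named("smoothed_cov") = Ss);
}
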