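// Likelihood core for the latent-class location-scale model.
//
// Data layout: one row per observation; subj0 is the 0-based subject ordinal
// of each observation; tu/tidx factor the time vector through its unique
// values so that exp(tau0 + tau1 * t) is evaluated once per unique time.
//
// Conditional on location class l and scale class s,
//   Y_ij ~ N(beta0_l + beta1_l * t_ij, exp(tau0_s + tau1_s * t_ij)),
// and the subject-level marginal likelihood sums the L x S grid weighted by
// the class probabilities. Everything is done in log space.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2PI = 1.837877066409345483560659472811;

// Per-subject conditional log-likelihood cube ll(i, l, s) plus, optionally,
// the sufficient statistics needed for the gradient of the marginal
// log-likelihood with respect to beta and tau.
static void cond_loglik_cube(const arma::vec& y, const arma::vec& tu,
                             const arma::uvec& tidx, const arma::uvec& subj0,
                             const int N, const arma::mat& beta,
                             const arma::mat& tau, arma::cube& ll,
                             const bool want_grad, arma::cube& G0,
                             arma::cube& G1, arma::cube& H0, arma::cube& H1) {
  const int L = beta.n_rows, S = tau.n_rows;
  const arma::uword M = y.n_elem;
  const arma::uword U = tu.n_elem;
  ll.zeros(N, L, S);
  if (want_grad) {
    G0.zeros(N, L, S); G1.zeros(N, L, S);
    H0.zeros(N, L, S); H1.zeros(N, L, S);
  }
  arma::vec lvu(U), ivu(U);
  for (int s = 0; s < S; ++s) {
    for (arma::uword u = 0; u < U; ++u) {
      lvu[u] = tau(s, 0) + tau(s, 1) * tu[u];
      ivu[u] = std::exp(-lvu[u]);
    }
    for (int l = 0; l < L; ++l) {
      const double b0 = beta(l, 0), b1 = beta(l, 1);
      for (arma::uword m = 0; m < M; ++m) {
        const arma::uword u = tidx[m];
        const double tm = tu[u];
        const double r = y[m] - b0 - b1 * tm;
        const double q = r * r * ivu[u];
        const int i = subj0[m];
        ll(i, l, s) += -0.5 * (LOG2PI + lvu[u] + q);
        if (want_grad) {
          const double g = r * ivu[u];
          const double h = 0.5 * (q - 1.0);
          G0(i, l, s) += g;       G1(i, l, s) += tm * g;
          H0(i, l, s) += h;       H1(i, l, s) += tm * h;
        }
      }
    }
  }
}

// Marginal log-likelihood, posterior class memberships and (optionally) the
// gradient with respect to beta (L x 2) and tau (S x 2). The gradient with
// respect to the class-probability logits is assembled in R from eta.
// [[Rcpp::export]]
List lcls_core(const arma::vec& y, const arma::vec& tu, const arma::uvec& tidx,
               const arma::uvec& subj0, const int N, const arma::mat& beta,
               const arma::mat& tau, const arma::vec& pi_loc,
               const arma::vec& pi_scale, const bool want_grad,
               const bool want_cond = false) {
  const int L = beta.n_rows, S = tau.n_rows;
  arma::cube ll, G0, G1, H0, H1;
  cond_loglik_cube(y, tu, tidx, subj0, N, beta, tau, ll, want_grad,
                   G0, G1, H0, H1);
  const arma::vec lpl = arma::log(pi_loc), lps = arma::log(pi_scale);
  arma::vec per(N);
  arma::mat eta_loc(N, L), eta_scale(N, S);
  arma::mat gbeta(L, 2, arma::fill::zeros), gtau(S, 2, arma::fill::zeros);
  for (int i = 0; i < N; ++i) {
    arma::mat a(L, S);
    for (int l = 0; l < L; ++l)
      for (int s = 0; s < S; ++s)
        a(l, s) = lpl[l] + lps[s] + ll(i, l, s);
    const double mx = a.max();
    arma::mat w = arma::exp(a - mx);
    const double sw = arma::accu(w);
    per[i] = mx + std::log(sw);
    w /= sw;
    eta_loc.row(i) = arma::sum(w, 1).t();
    eta_scale.row(i) = arma::sum(w, 0);
    if (want_grad) {
      for (int l = 0; l < L; ++l) {
        for (int s = 0; s < S; ++s) {
          const double wls = w(l, s);
          gbeta(l, 0) += wls * G0(i, l, s);
          gbeta(l, 1) += wls * G1(i, l, s);
          gtau(s, 0)  += wls * H0(i, l, s);
          gtau(s, 1)  += wls * H1(i, l, s);
        }
      }
    }
  }
  List out = List::create(
    _["per_subject"] = per,
    _["total"] = arma::accu(per),
    _["eta_loc"] = eta_loc,
    _["eta_scale"] = eta_scale);
  if (want_grad) {
    out["gbeta"] = gbeta;
    out["gtau"] = gtau;
  }
  if (want_cond) out["cond_loglik"] = ll;
  return out;
}

// Per-draw, per-subject marginal log-likelihood (draws x N) and the
// across-draw average of the posterior membership matrices. Draw columns are
// laid out as beta0(L), beta1(L), tau0(S), tau1(S), pi_loc(L), pi_scale(S).
// [[Rcpp::export]]
List lcls_pointwise(const arma::vec& y, const arma::vec& tu,
                    const arma::uvec& tidx, const arma::uvec& subj0,
                    const int N, const arma::mat& draws, const int L,
                    const int S) {
  const int D = draws.n_rows;
  const arma::uword M = y.n_elem;
  const arma::uword U = tu.n_elem;
  arma::mat pw(D, N);
  arma::mat eta_loc(N, L, arma::fill::zeros);
  arma::mat eta_scale(N, S, arma::fill::zeros);
  arma::cube ll(N, L, S);
  arma::vec lvu(U), ivu(U);
  for (int d = 0; d < D; ++d) {
    ll.zeros();
    for (int s = 0; s < S; ++s) {
      const double t0 = draws(d, 2 * L + s), t1 = draws(d, 2 * L + S + s);
      for (arma::uword u = 0; u < U; ++u) {
        lvu[u] = t0 + t1 * tu[u];
        ivu[u] = std::exp(-lvu[u]);
      }
      for (int l = 0; l < L; ++l) {
        const double b0 = draws(d, l), b1 = draws(d, L + l);
        for (arma::uword m = 0; m < M; ++m) {
          const arma::uword u = tidx[m];
          const double r = y[m] - b0 - b1 * tu[u];
          ll(subj0[m], l, s) += -0.5 * (LOG2PI + lvu[u] + r * r * ivu[u]);
        }
      }
    }
    arma::vec lpl(L), lps(S);
    for (int l = 0; l < L; ++l) lpl[l] = std::log(draws(d, 2 * L + 2 * S + l));
    for (int s = 0; s < S; ++s)
      lps[s] = std::log(draws(d, 2 * L + 2 * S + L + s));
    for (int i = 0; i < N; ++i) {
      arma::mat a(L, S);
      for (int l = 0; l < L; ++l)
        for (int s = 0; s < S; ++s)
          a(l, s) = lpl[l] + lps[s] + ll(i, l, s);
      const double mx = a.max();
      arma::mat w = arma::exp(a - mx);
      const double sw = arma::accu(w);
      pw(d, i) = mx + std::log(sw);
      w /= sw;
      eta_loc.row(i) += arma::sum(w, 1).t();
      eta_scale.row(i) += arma::sum(w, 0);
    }
  }
  eta_loc /= D;
  eta_scale /= D;
  return List::create(_["pointwise"] = pw, _["eta_loc"] = eta_loc,
                      _["eta_scale"] = eta_scale);
}
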