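// Likelihood and posterior kernels for the multivariate adaptive
// shrinkage meta-analysis. Component layout everywhere: component 0 is the
// point-mass null (covariance V_j only), followed by K*G components
// ordered U-major: (U_1,w_1), (U_1,w_2), ..., (U_K,w_G).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double logdmvnorm_chol(const vec& b, const mat& Sigma, bool& ok) {
  mat L;
  ok = chol(L, Sigma, "lower");
  if (!ok) return -datum::inf;
  vec z = solve(trimatl(L), b);
  double logdet = 2.0 * sum(log(L.diag()));
  return -0.5 * (b.n_elem * std::log(2.0 * datum::pi) + logdet +
                 dot(z, z));
}

// [[Rcpp::export(name = ".mash_loglik_cpp")]]
arma::mat mash_loglik_cpp(const arma::mat& Bhat, const arma::mat& Shat,
                          const arma::mat& C, const Rcpp::List& Ulist,
                          const arma::vec& omegas) {
  const uword J = Bhat.n_rows, R = Bhat.n_cols;
  const uword K = Ulist.size(), G = omegas.n_elem;
  std::vector<mat> Us(K);
  for (uword k = 0; k < K; ++k) Us[k] = Rcpp::as<mat>(Ulist[k]);
  mat LL(J, 1 + K * G);
  for (uword j = 0; j < J; ++j) {
    vec s = Shat.row(j).t();
    mat V = diagmat(s) * C * diagmat(s);
    vec b = Bhat.row(j).t();
    bool ok;
    LL(j, 0) = logdmvnorm_chol(b, V, ok);
    for (uword k = 0; k < K; ++k) {
      for (uword g = 0; g < G; ++g) {
        mat Sigma = V + omegas(g) * Us[k];
        double ll = logdmvnorm_chol(b, Sigma, ok);
        if (!ok) {
          // nudge a semi-definite matrix onto the PD cone
          mat Sigma2 = Sigma + 1e-8 * trace(Sigma) / R * eye(R, R);
          ll = logdmvnorm_chol(b, Sigma2, ok);
        }
        LL(j, 1 + k * G + g) = ll;
      }
    }
  }
  return LL;
}

// [[Rcpp::export(name = ".mash_posterior_cpp")]]
Rcpp::List mash_posterior_cpp(const arma::mat& Bhat, const arma::mat& Shat,
                              const arma::mat& C, const Rcpp::List& Ulist,
                              const arma::vec& omegas, const arma::vec& pi,
                              const arma::mat& LL) {
  const uword J = Bhat.n_rows, R = Bhat.n_cols;
  const uword K = Ulist.size(), G = omegas.n_elem;
  const double tiny = 1e-12;
  std::vector<mat> Us(K);
  for (uword k = 0; k < K; ++k) Us[k] = Rcpp::as<mat>(Ulist[k]);
  mat post_mean(J, R, fill::zeros), post_m2(J, R, fill::zeros);
  mat p_neg(J, R, fill::zeros), p_pos(J, R, fill::zeros),
      p_zero(J, R, fill::zeros);
  vec logpi(pi.n_elem);
  for (uword c = 0; c < pi.n_elem; ++c)
    logpi(c) = pi(c) > 0 ? std::log(pi(c)) : -datum::inf;
  for (uword j = 0; j < J; ++j) {
    vec lw = LL.row(j).t() + logpi;
    double m = lw.max();
    vec gam = exp(lw - m);
    gam /= accu(gam);
    vec s = Shat.row(j).t();
    mat V = diagmat(s) * C * diagmat(s);
    vec b = Bhat.row(j).t();
    // null component: point mass at zero in every condition
    p_zero.row(j) += gam(0) * rowvec(R, fill::ones);
    for (uword k = 0; k < K; ++k) {
      for (uword g = 0; g < G; ++g) {
        double gjc = gam(1 + k * G + g);
        if (gjc < 1e-15) continue;
        mat W = omegas(g) * Us[k];
        mat Sigma = V + W;
        mat A;
        if (!solve(A, Sigma, W)) continue;   // A = Sigma^{-1} W
        vec mu1 = A.t() * b;                 // W Sigma^{-1} b
        mat Sig1 = W - W * A;                // W - W Sigma^{-1} W
        for (uword r = 0; r < R; ++r) {
          double v1 = std::max(Sig1(r, r), 0.0);
          double mu = mu1(r);
          post_mean(j, r) += gjc * mu;
          post_m2(j, r) += gjc * (mu * mu + v1);
          if (v1 < tiny) {
            if (std::abs(mu) < tiny) p_zero(j, r) += gjc;
            else if (mu < 0) p_neg(j, r) += gjc;
            else p_pos(j, r) += gjc;
          } else {
            double pn = R::pnorm(0.0, mu, std::sqrt(v1), 1, 0);
            p_neg(j, r) += gjc * pn;
            p_pos(j, r) += gjc * (1.0 - pn);
          }
        }
      }
    }
  }
  mat post_sd = sqrt(clamp(post_m2 - square(post_mean), 0.0, datum::inf));
  mat lfsr = min(p_neg + p_zero, p_pos + p_zero);
  return Rcpp::List::create(Rcpp::Named("post_mean") = post_mean,
                            Rcpp::Named("post_sd") = post_sd,
                            Rcpp::Named("lfsr") = lfsr,
                            Rcpp::Named("p_neg") = p_neg,
                            Rcpp::Named("p_pos") = p_pos,
                            Rcpp::Named("p_zero") = p_zero);
}
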