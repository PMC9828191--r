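#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Draw from N(Q^{-1} b, Q^{-1}) given the precision matrix Q.
static arma::vec draw_mvn_prec(const arma::vec& b, const arma::mat& Q) {
  arma::mat R;
  if (!arma::chol(R, Q))
    stop("conditional precision matrix is not positive definite");
  arma::vec mu = arma::solve(arma::trimatu(R),
                             arma::solve(arma::trimatl(R.t()), b));
  arma::vec z(mu.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = norm_rand();
  return mu + arma::solve(arma::trimatu(R), z);
}

// Gibbs sampler for the bilinear reduced-rank selection model
//   y_i = alpha + x_i' beta_std + sum_k beta_axis_k (z_i' w_k) + eps_i,
//   eps_i ~ N(0, sigma2),
// with N(0, prior_sd_beta^2) priors on intercept and all slopes,
// N(0, prior_sd_w^2) priors on raw axis weights, and an
// inverse-gamma(shape0, scale0) prior on sigma2. Covariates X and Z are
// expected pre-standardized. With rank = 0 this reduces to Bayesian
// ridge-type multiple regression (no weight block).
//
// Updates are conditionally conjugate: given the weights the model is
// linear in (alpha, beta), and given the slopes it is linear in each
// axis's weight vector. Uses R's RNG so set.seed() governs the chain.
// [[Rcpp::export]]
List rrr_gibbs_chain(const arma::vec& y, const arma::mat& X, const arma::mat& Z,
                     const int rank, const double prior_sd_beta,
                     const double prior_sd_w, const double shape0,
                     const double scale0, const int n_warmup,
                     const int n_samples, const int thin) {
  const arma::uword n  = y.n_elem;
  const arma::uword px = X.n_cols;
  const arma::uword q  = Z.n_cols;
  const arma::uword p  = 1 + px + (arma::uword)rank;

  arma::mat D(n, p, arma::fill::ones);
  if (px > 0) D.cols(1, px) = X;

  arma::mat ZtZ;
  if (rank > 0) ZtZ = Z.t() * Z;

  const double tb2 = prior_sd_beta * prior_sd_beta;
  const double tw2 = prior_sd_w * prior_sd_w;

  // init: weights from their prior, slopes at 0, sigma2 at var(y)
  arma::mat W((arma::uword)rank, q);
  for (arma::uword k = 0; k < (arma::uword)rank; ++k)
    for (arma::uword l = 0; l < q; ++l)
      W(k, l) = prior_sd_w * norm_rand();

  arma::vec beta(p, arma::fill::zeros);
  double sigma2 = arma::var(y);
  if (!(sigma2 > 0.0)) sigma2 = 1.0;

  const int n_iter = n_warmup + n_samples * thin;
  arma::mat beta_out(n_samples, p);
  arma::mat w_out(n_samples, (arma::uword)rank * q);
  arma::vec sigma2_out(n_samples);

  int keep = 0;
  for (int it = 0; it < n_iter; ++it) {
    if (rank > 0) D.cols(1 + px, p - 1) = Z * W.t();

    // (a) joint normal update of intercept + all slopes
    arma::mat Qb = D.t() * D / sigma2;
    Qb.diag() += 1.0 / tb2;
    beta = draw_mvn_prec(D.t() * y / sigma2, Qb);

    // (b) per-axis normal update of the weight vector
    if (rank > 0) {
      arma::vec base = y - beta(0);
      if (px > 0) base -= X * beta.subvec(1, px);
      for (arma::uword k = 0; k < (arma::uword)rank; ++k) {
        arma::vec r = base;
        for (arma::uword j = 0; j < (arma::uword)rank; ++j)
          if (j != k) r -= beta(1 + px + j) * (Z * W.row(j).t());
        const double bk = beta(1 + px + k);
        arma::mat Qw = (bk * bk / sigma2) * ZtZ;
        Qw.diag() += 1.0 / tw2;
        arma::vec bw = (bk / sigma2) * (Z.t() * r);
        W.row(k) = draw_mvn_prec(bw, Qw).t();
      }
      D.cols(1 + px, p - 1) = Z * W.t();
    }

    // (c) inverse-gamma update of the residual variance
    arma::vec resid = y - D * beta;
    const double ssr = arma::dot(resid, resid);
    const double g = R::rgamma(shape0 + 0.5 * (double)n,
                               1.0 / (scale0 + 0.5 * ssr));
    sigma2 = 1.0 / g;

    if (!std::isfinite(sigma2) || !beta.is_finite() ||
        (rank > 0 && !W.is_finite()))
      stop("sampler reached a non-finite state at iteration %d", it + 1);

    if (it >= n_warmup && ((it - n_warmup) % thin == 0)) {
      beta_out.row(keep) = beta.t();
      if (rank > 0) w_out.row(keep) = arma::vectorise(W, 1);
      sigma2_out(keep) = sigma2;
      ++keep;
    }
  }

  return List::create(_["beta"] = beta_out,
                      _["weights"] = w_out,
                      _["sigma2"] = sigma2_out);
}
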