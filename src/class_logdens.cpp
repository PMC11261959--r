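// Multivariate-normal class log-densities for twin-pair mixture likelihoods.
// The per-pair, per-class Gaussian evaluation is the only hot loop in the
// package; everything else (path algebra, optimisation, posteriors) stays in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// X: N x d data matrix; mus: d x C matrix of class means; sigmas: d x d x C
// cube of class covariances.  Returns N x C matrix of log phi_c(x_i).
// A non-positive-definite class covariance raises an error naming the class.
// [[Rcpp::export]]
arma::mat cpp_class_logdens(const arma::mat& X, const arma::mat& mus,
                            const arma::cube& sigmas) {
  const arma::uword N = X.n_rows, d = X.n_cols, C = mus.n_cols;
  if (sigmas.n_rows != d || sigmas.n_cols != d || sigmas.n_slices != C)
    stop("dimension mismatch between data, means and covariances");
  arma::mat out(N, C);
  const double ld2pi = d * std::log(2.0 * M_PI);
  for (arma::uword c = 0; c < C; ++c) {
    arma::mat R;
    if (!arma::chol(R, sigmas.slice(c)))
      stop("covariance matrix of class %d is not positive definite", (int)(c + 1));
    // Solve R' z = (x - mu)' for each row: z = R'^{-1} (x - mu)'
    arma::mat centered = X.each_row() - mus.col(c).t();   // N x d
    arma::mat Z = arma::solve(arma::trimatl(R.t()), centered.t()); // d x N
    arma::rowvec quad = arma::sum(arma::square(Z), 0);    // 1 x N
    double logdet = arma::accu(arma::log(R.diag()));      // 0.5*log|Sigma|
    out.col(c) = (-0.5 * (ld2pi + quad.t())) - logdet;
  }
  return out;
}

// Total mixture log-likelihood contribution of one zygosity group:
// sum_i log sum_c exp(logw_c + log phi_c(x_i)), with log-sum-exp
// stabilization.  logw holds the log mixing proportions.
// [[Rcpp::export]]
double cpp_mix_loglik(const arma::mat& X, const arma::mat& mus,
                      const arma::cube& sigmas, const arma::vec& logw) {
  arma::mat ld = cpp_class_logdens(X, mus, sigmas);
  ld.each_row() += logw.t();
  arma::vec m = arma::max(ld, 1);
  arma::vec s = arma::sum(arma::exp(ld.each_col() - m), 1);
  return arma::accu(m + arma::log(s));
}
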