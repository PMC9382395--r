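// Ridge-penalized logistic regression by iteratively reweighted least squares,
// with warm starts along a decreasing lambda path and K-fold cross-validated
// deviance. Objective per observation matches glmnet's convention for
// alpha = 0: (1/n) * sum(-loglik) + (lambda/2) * ||beta_std||^2, with the
// penalty applied on the standardized-predictor scale (sd with denominator n)
// and the intercept left unpenalized.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// One IRLS solve at fixed lambda on an already-standardized design.
// X1: n x (p+1) with leading column of ones. beta is used as warm start and
// overwritten. Returns true on convergence.
// Newton with periodic Hessian refresh: the Hessian (and its Cholesky
// factor) is rebuilt in the outer loop, then reused for a few cheap
// fixed-Hessian score steps. The fixed point solves the exact score
// equation, so the converged solution does not depend on the reuse; warm
// starts along the lambda path keep the reused Hessian accurate.
static bool irls_fixed_lambda(const mat& X1, const vec& y, double nlam,
                              vec& beta, double tol, int maxit) {
  const uword p1 = X1.n_cols;
  vec penalty(p1, fill::value(nlam));
  penalty(0) = 0.0;  // intercept unpenalized
  vec eta = X1 * beta;
  vec mu = 1.0 / (1.0 + exp(-eta));
  for (int outer = 0; outer < maxit; ++outer) {
    vec w = clamp(mu % (1.0 - mu), 1e-9, 0.25);
    mat Xw = X1.each_col() % sqrt(w);
    mat H = Xw.t() * Xw;  // syrk path
    H.diag() += penalty;
    mat L;
    if (!chol(L, H, "lower")) return false;
    double last = datum::inf;
    for (int inner = 0; inner < 10; ++inner) {
      vec g = X1.t() * (y - mu) - penalty % beta;
      vec delta = solve(trimatu(L.t()), solve(trimatl(L), g));
      delta = clamp(delta, -5.0, 5.0);
      beta += delta;
      eta = X1 * beta;
      mu = 1.0 / (1.0 + exp(-eta));
      double d = max(abs(delta));
      if (d < tol) return true;
      if (d > 0.5 * last) break;  // chord step stalling: refresh Hessian
      last = d;
    }
  }
  return false;
}

// Standardize columns of X with mean/sd(denominator n) computed from the rows
// in `rows`; constant columns get sd = 1.
static void col_stats(const mat& X, vec& mean_out, vec& sd_out) {
  mean_out = conv_to<vec>::from(arma::mean(X, 0).t());
  mat Xc = X.each_row() - mean_out.t();
  vec v = conv_to<vec>::from(arma::mean(square(Xc), 0).t());
  sd_out = sqrt(v);
  sd_out.replace(0.0, 1.0);
  sd_out(find(sd_out < 1e-12)).fill(1.0);
}

static double binomial_deviance(const vec& y, const vec& eta) {
  vec mu = 1.0 / (1.0 + exp(-eta));
  mu = clamp(mu, 1e-10, 1.0 - 1e-10);
  return -2.0 * accu(y % log(mu) + (1.0 - y) % log(1.0 - mu));
}

// Fit the full lambda path (lambda must be sorted decreasing) on (X, y).
// Returns coefficients on the ORIGINAL predictor scale: (p+1) x nlambda,
// row 0 the intercept.
// [[Rcpp::export]]
Rcpp::List ridge_logit_path_cpp(const arma::mat& X, const arma::vec& y,
                                const arma::vec& lambda, double tol,
                                int maxit) {
  const uword n = X.n_rows, p = X.n_cols, nl = lambda.n_elem;
  vec mu_x, sd_x;
  col_stats(X, mu_x, sd_x);
  mat Xs = X.each_row() - mu_x.t();
  Xs.each_row() /= sd_x.t();
  mat X1 = join_rows(ones<vec>(n), Xs);

  double ybar = arma::mean(y);
  ybar = std::min(std::max(ybar, 1e-10), 1.0 - 1e-10);
  vec beta(p + 1, fill::zeros);
  beta(0) = std::log(ybar / (1.0 - ybar));

  mat coefs(p + 1, nl);
  Rcpp::LogicalVector converged(nl);
  for (uword j = 0; j < nl; ++j) {
    converged[j] = irls_fixed_lambda(X1, y, n * lambda(j), beta, tol, maxit);
    // back-transform to the original scale
    vec b_orig = beta.subvec(1, p) / sd_x;
    coefs(0, j) = beta(0) - dot(b_orig, mu_x);
    coefs.submat(1, j, p, j) = b_orig;
  }
  return Rcpp::List::create(Rcpp::Named("coef") = coefs,
                            Rcpp::Named("converged") = converged);
}

// K-fold cross-validated mean binomial deviance per lambda. foldid is 1-based.
// [[Rcpp::export]]
arma::vec cv_ridge_logit_cpp(const arma::mat& X, const arma::vec& y,
                             const arma::vec& lambda,
                             const arma::ivec& foldid, int nfolds,
                             double tol, int maxit) {
  const uword p = X.n_cols, nl = lambda.n_elem;
  vec dev_total(nl, fill::zeros);
  for (int f = 1; f <= nfolds; ++f) {
    uvec idx_val = find(foldid == f);
    uvec idx_tr = find(foldid != f);
    mat Xtr = X.rows(idx_tr);
    vec ytr = y.elem(idx_tr);
    mat Xval = X.rows(idx_val);
    vec yval = y.elem(idx_val);

    vec mu_x, sd_x;
    col_stats(Xtr, mu_x, sd_x);
    mat Xs = Xtr.each_row() - mu_x.t();
    Xs.each_row() /= sd_x.t();
    mat X1 = join_rows(ones<vec>(Xtr.n_rows), Xs);
    mat Xvs = Xval.each_row() - mu_x.t();
    Xvs.each_row() /= sd_x.t();

    double ybar = arma::mean(ytr);
    ybar = std::min(std::max(ybar, 1e-10), 1.0 - 1e-10);
    vec beta(p + 1, fill::zeros);
    beta(0) = std::log(ybar / (1.0 - ybar));

    for (uword j = 0; j < nl; ++j) {
      irls_fixed_lambda(X1, ytr, Xtr.n_rows * lambda(j), beta, tol, maxit);
      vec eta_val = beta(0) + Xvs * beta.subvec(1, p);
      dev_total(j) += binomial_deviance(yval, eta_val);
    }
  }
  return dev_total / static_cast<double>(X.n_rows);
}
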