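// Hot kernels for test-set evaluation: rank-sum concordance with midranks,
// and the two small offset logistic regressions (intercept-only with offset;
// intercept + slope on a linear predictor), fit by Newton iterations.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// AUROC as concordance over event/nonevent pairs with ties counted 1/2
// (rank-sum with midranks).
// [[Rcpp::export]]
double auroc_cpp(const arma::vec& score, const arma::ivec& y) {
  const uword n = score.n_elem;
  uvec ord = sort_index(score);
  vec ranks(n);
  uword i = 0;
  while (i < n) {
    uword j = i;
    while (j + 1 < n && score(ord(j + 1)) == score(ord(i))) ++j;
    double mid = 0.5 * (static_cast<double>(i) + static_cast<double>(j)) + 1.0;
    for (uword k = i; k <= j; ++k) ranks(ord(k)) = mid;
    i = j + 1;
  }
  double n1 = 0, rsum = 0;
  for (uword k = 0; k < n; ++k)
    if (y(k) == 1) { n1 += 1.0; rsum += ranks(k); }
  double n0 = static_cast<double>(n) - n1;
  if (n1 == 0.0 || n0 == 0.0) return NA_REAL;
  return (rsum - n1 * (n1 + 1.0) / 2.0) / (n1 * n0);
}

static inline double plogis_(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// MLE of a in logit P(Y=1) = a + offset (Newton with step cap).
// [[Rcpp::export]]
double offset_intercept_mle_cpp(const arma::vec& offset, const arma::vec& y,
                                double tol, int maxit) {
  const double n = static_cast<double>(y.n_elem);
  const double ybar = accu(y) / n;
  double a = 0.0;
  for (int it = 0; it < maxit; ++it) {
    double smu = 0.0, sw = 0.0;
    for (uword i = 0; i < offset.n_elem; ++i) {
      double mu = plogis_(a + offset(i));
      smu += mu;
      sw += mu * (1.0 - mu);
    }
    double h = sw / n;
    if (h < 1e-14) break;
    double step = (ybar - smu / n) / h;
    if (std::abs(step) > 10.0) step = step > 0 ? 10.0 : -10.0;
    a += step;
    if (std::abs(step) < tol) break;
  }
  return a;
}

static double neg2ll(const vec& lp, const vec& y, double a, double b) {
  double out = 0.0;
  for (uword i = 0; i < lp.n_elem; ++i) {
    double eta = a + b * lp(i);
    // -2 * (y*eta - log(1 + exp(eta))), stable
    double lse = eta > 0 ? eta + std::log1p(std::exp(-eta))
                         : std::log1p(std::exp(eta));
    out += -2.0 * (y(i) * eta - lse);
  }
  return out;
}

// MLE of (a, b) in logit P(Y=1) = a + b * lp; Newton with step-halving on
// the deviance. Returns (a, b).
// [[Rcpp::export]]
arma::vec logistic_two_param_mle_cpp(const arma::vec& lp, const arma::vec& y,
                                     double tol, int maxit) {
  double a = 0.0, b = 1.0;
  bool have_dev = false;
  double dev = 0.0;
  for (int it = 0; it < maxit; ++it) {
    double g0 = 0, g1 = 0, h00 = 0, h01 = 0, h11 = 0;
    for (uword i = 0; i < lp.n_elem; ++i) {
      double mu = plogis_(a + b * lp(i));
      double w = mu * (1.0 - mu);
      if (w < 1e-12) w = 1e-12;
      double r = y(i) - mu;
      g0 += r; g1 += r * lp(i);
      h00 += w; h01 += w * lp(i); h11 += w * lp(i) * lp(i);
    }
    double det = h00 * h11 - h01 * h01;
    if (std::abs(det) < 1e-300) break;
    double da = (h11 * g0 - h01 * g1) / det;
    double db = (h00 * g1 - h01 * g0) / det;
    double moved;
    if (std::max(std::abs(da), std::abs(db)) <= 1.0 && it < 30) {
      // small trusted Newton step: concave log-likelihood, no line search
      a += da; b += db;
      moved = std::max(std::abs(da), std::abs(db));
      have_dev = false;
    } else {
      if (!have_dev) dev = neg2ll(lp, y, a, b);
      double step = 1.0, dev_new;
      for (;;) {
        dev_new = neg2ll(lp, y, a + step * da, b + step * db);
        if (dev_new <= dev + 1e-12 || step < 1e-8) break;
        step *= 0.5;
      }
      a += step * da; b += step * db;
      moved = std::max(std::abs(step * da), std::abs(step * db));
      dev = dev_new;
      have_dev = true;
    }
    if (moved < tol) break;
  }
  vec out(2); out(0) = a; out(1) = b;
  return out;
}
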