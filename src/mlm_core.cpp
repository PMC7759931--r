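// Profiled-deviance optimization for the single-random-intercept Gaussian
// mixed model. For a fixed variance ratio theta = sigma2_patient /
// sigma2_resid, the GLS solution and residual variance are closed-form via
// blockwise Woodbury identities on per-group sufficient statistics; the
// deviance is minimized over log(theta) by golden-section search. Called in
// tight Monte-Carlo loops, hence compiled.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static double dev_eval(const mat& A, const vec& b, double yy, const mat& G,
                       const vec& h, const vec& s, double sumlogw,
                       int n, int p, double theta, bool reml) {
  vec c = theta / (1.0 + theta * s);
  mat XtVX = A - G.t() * (G.each_col() % c);
  vec XtVy = b - G.t() * (c % h);
  double ytVy = yy - dot(c, h % h);
  mat R;
  if (!chol(R, XtVX)) return datum::inf;
  vec beta = solve(trimatu(R), solve(trimatl(R.t()), XtVy));
  double rss = ytVy - dot(beta, XtVy);
  if (rss < 0) rss = 0;
  double logdetV = sum(log1p(theta * s)) - sumlogw;
  if (reml) {
    double s2 = std::max(rss / (n - p), 1e-300);
    return (n - p) * std::log(2.0 * M_PI * s2) + logdetV +
           2.0 * sum(log(R.diag())) + (n - p);
  }
  double s2 = std::max(rss / n, 1e-300);
  return n * std::log(2.0 * M_PI * s2) + logdetV + n;
}

// [[Rcpp::export]]
Rcpp::List mlm_core_cpp(const arma::mat& A, const arma::vec& b, double yy,
                        const arma::mat& G, const arma::vec& h,
                        const arma::vec& s, double sumlogw,
                        int n, int p, bool reml) {
  const double lo0 = -30.0, hi0 = 15.0;
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double lo = lo0, hi = hi0;
  double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
  double f1 = dev_eval(A, b, yy, G, h, s, sumlogw, n, p, std::exp(x1), reml);
  double f2 = dev_eval(A, b, yy, G, h, s, sumlogw, n, p, std::exp(x2), reml);
  while (hi - lo > 1e-9) {
    if (f1 <= f2) {
      hi = x2; x2 = x1; f2 = f1;
      x1 = hi - gr * (hi - lo);
      f1 = dev_eval(A, b, yy, G, h, s, sumlogw, n, p, std::exp(x1), reml);
    } else {
      lo = x1; x1 = x2; f1 = f2;
      x2 = lo + gr * (hi - lo);
      f2 = dev_eval(A, b, yy, G, h, s, sumlogw, n, p, std::exp(x2), reml);
    }
  }
  double ltheta = (f1 <= f2) ? x1 : x2;
  double theta = std::exp(ltheta);
  double dev = std::min(f1, f2);
  // boundary: no between-group variance
  double dev0 = dev_eval(A, b, yy, G, h, s, sumlogw, n, p, 0.0, reml);
  if (dev0 <= dev + 1e-10) { theta = 0.0; dev = dev0; }

  // recompute pieces at the optimum
  vec c = theta / (1.0 + theta * s);
  mat XtVX = A - G.t() * (G.each_col() % c);
  vec XtVy = b - G.t() * (c % h);
  double ytVy = yy - dot(c, h % h);
  mat R = chol(XtVX);
  vec beta = solve(trimatu(R), solve(trimatl(R.t()), XtVy));
  double rss = ytVy - dot(beta, XtVy);
  if (rss < 0) rss = 0;
  return Rcpp::List::create(
    Rcpp::Named("theta") = theta,
    Rcpp::Named("deviance") = dev,
    Rcpp::Named("beta") = beta,
    Rcpp::Named("rss") = rss,
    Rcpp::Named("cholXtVX") = R);
}
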