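#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Fast weighted least-squares / IRLS engines for the ensemble hot loops.
// family codes: 0 = gaussian (identity link), 1 = binomial (logit link).
// Rank-deficient designs make the normal-equation solve fail; callers fall
// back to stats::glm.fit, which drops later-entered aliased columns.

static const double MU_EPS = 1e-10;
static const double COEF_CAP = 30.0; // |eta| beyond this signals separation

static double gauss_loglik(double n, double rss) {
  double s2 = rss / n;
  if (s2 < 1e-300) s2 = 1e-300;
  return -0.5 * n * (std::log(2.0 * M_PI * s2) + 1.0);
}

static double binom_loglik(const arma::vec& y, const arma::vec& mu) {
  double ll = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i) {
    double m = std::min(std::max(mu[i], MU_EPS), 1.0 - MU_EPS);
    ll += y[i] * std::log(m) + (1.0 - y[i]) * std::log(1.0 - m);
  }
  return ll;
}

// Core fitter. Returns false when the solve fails (collinearity).
// `init` optionally warm-starts the IRLS iterations (binomial).
static bool fit_core(const arma::mat& X, const arma::vec& y, int family,
                     int maxit, double tol,
                     arma::vec& beta, double& loglik, bool& converged,
                     const arma::vec* init = 0) {
  const arma::uword n = X.n_rows;
  beta.zeros(X.n_cols);
  if (family == 0) {
    arma::mat XtX = X.t() * X;
    arma::vec Xty = X.t() * y;
    bool ok = arma::solve(beta, XtX, Xty,
                          arma::solve_opts::no_approx + arma::solve_opts::likely_sympd);
    if (!ok || !beta.is_finite()) return false;
    arma::vec r = y - X * beta;
    loglik = gauss_loglik((double)n, arma::dot(r, r));
    converged = true;
    return true;
  }
  // binomial IRLS
  arma::vec eta(n, arma::fill::zeros), mu(n), w(n), z(n), bnew;
  if (init && init->n_elem == X.n_cols) {
    beta = *init;
    eta = X * beta;
    eta = arma::clamp(eta, -4.0 * COEF_CAP, 4.0 * COEF_CAP);
  }
  double dev_old = R_PosInf;
  converged = false;
  for (int it = 0; it < maxit; ++it) {
    mu = 1.0 / (1.0 + arma::exp(-eta));
    mu = arma::clamp(mu, MU_EPS, 1.0 - MU_EPS);
    w = mu % (1.0 - mu);
    z = eta + (y - mu) / w;
    arma::mat Xw = X.each_col() % w;
    arma::mat XtWX = X.t() * Xw;
    arma::vec XtWz = Xw.t() * z;
    bool ok = arma::solve(bnew, XtWX, XtWz,
                          arma::solve_opts::no_approx + arma::solve_opts::likely_sympd);
    if (!ok || !bnew.is_finite()) {
      if (it == 0) return false; // collinear design
      break;                     // diverged late: keep last iterate, flag
    }
    beta = bnew;
    eta = X * beta;
    if (arma::abs(eta).max() > 4.0 * COEF_CAP) break; // separation
    mu = 1.0 / (1.0 + arma::exp(-eta));
    double dev = -2.0 * binom_loglik(y, mu);
    if (std::fabs(dev - dev_old) < tol * (std::fabs(dev) + 0.1)) {
      converged = true;
      break;
    }
    dev_old = dev;
  }
  mu = 1.0 / (1.0 + arma::exp(-X * beta));
  loglik = binom_loglik(y, mu);
  if (converged && arma::abs(X * beta).max() > COEF_CAP) converged = false;
  return true;
}

// [[Rcpp::export]]
List cpp_glm_fit(const arma::mat& X, const arma::vec& y, int family,
                 int maxit, double tol) {
  arma::vec beta;
  double loglik = NA_REAL;
  bool converged = false;
  bool ok = fit_core(X, y, family, maxit, tol, beta, loglik, converged);
  return List::create(_["ok"] = ok,
                      _["coefficients"] = beta,
                      _["loglik"] = loglik,
                      _["converged"] = converged);
}

// AIC of the current design augmented by each candidate column in turn.
// Only numerically failed fits (collinear solve) report +Inf; separated
// fits keep their (near-saturated) likelihood, as stepwise GLM selection
// does, so a perfectly predictive candidate is selected rather than
// discarded.
// [[Rcpp::export]]
NumericVector cpp_forward_step(const arma::mat& Xcur, const arma::mat& cand,
                               const arma::vec& y, int family,
                               int maxit, double tol,
                               const arma::vec& beta_cur) {
  const arma::uword p = Xcur.n_cols;
  NumericVector out(cand.n_cols);
  arma::mat X(Xcur.n_rows, p + 1);
  X.cols(0, p - 1) = Xcur;
  arma::vec beta, init(p + 1, arma::fill::zeros);
  bool warm = (beta_cur.n_elem == p);
  if (warm) init.head(p) = beta_cur;
  double loglik;
  bool converged;
  for (arma::uword j = 0; j < cand.n_cols; ++j) {
    X.col(p) = cand.col(j);
    bool ok = fit_core(X, y, family, maxit, tol, beta, loglik, converged,
                       warm ? &init : 0);
    out[j] = (ok && R_finite(loglik))
                 ? -2.0 * loglik + 2.0 * (double)(p + 1)
                 : R_PosInf;
  }
  return out;
}

// |Wald z| of the slope in a univariate logistic fit, per candidate column.
// Zero-variance columns and failed/separated fits score 0.
// [[Rcpp::export]]
NumericVector cpp_univariate_wald(const arma::mat& cand, const arma::vec& y,
                                  int maxit, double tol) {
  const arma::uword n = cand.n_rows;
  NumericVector out(cand.n_cols);
  for (arma::uword j = 0; j < cand.n_cols; ++j) {
    arma::vec x = cand.col(j);
    double v = arma::var(x);
    if (!R_finite(v) || v < 1e-14) { out[j] = 0.0; continue; }
    double b0 = 0.0, b1 = 0.0;
    bool converged = false;
    double dev_old = R_PosInf, i11 = 0.0;
    for (int it = 0; it < maxit; ++it) {
      double s0 = 0, s1 = 0, s2 = 0, r0 = 0, r1 = 0, dev = 0;
      for (arma::uword i = 0; i < n; ++i) {
        double eta = b0 + b1 * x[i];
        double mu = 1.0 / (1.0 + std::exp(-eta));
        mu = std::min(std::max(mu, MU_EPS), 1.0 - MU_EPS);
        double w = mu * (1.0 - mu);
        double res = y[i] - mu;
        s0 += w; s1 += w * x[i]; s2 += w * x[i] * x[i];
        r0 += res; r1 += res * x[i];
        dev += -2.0 * (y[i] * std::log(mu) + (1.0 - y[i]) * std::log(1.0 - mu));
      }
      double det = s0 * s2 - s1 * s1;
      if (det < 1e-12 * s0 * s2 || !R_finite(det)) { converged = false; break; }
      b0 += (s2 * r0 - s1 * r1) / det;
      b1 += (-s1 * r0 + s0 * r1) / det;
      i11 = s0 / det; // [2,2] of (X'WX)^{-1} at previous weights; refreshed below
      if (std::fabs(b0) > 4.0 * COEF_CAP || std::fabs(b1 * std::sqrt(v) * 4.0) > 16.0 * COEF_CAP) {
        converged = false; break;
      }
      if (std::fabs(dev - dev_old) < tol * (std::fabs(dev) + 0.1)) {
        converged = true; break;
      }
      dev_old = dev;
    }
    if (!converged) { out[j] = 0.0; continue; }
    // recompute the information at the final estimate
    double s0 = 0, s1 = 0, s2 = 0;
    bool pinned = false;
    for (arma::uword i = 0; i < n; ++i) {
      double eta = b0 + b1 * x[i];
      if (std::fabs(eta) > COEF_CAP) pinned = true;
      double mu = 1.0 / (1.0 + std::exp(-eta));
      mu = std::min(std::max(mu, MU_EPS), 1.0 - MU_EPS);
      double w = mu * (1.0 - mu);
      s0 += w; s1 += w * x[i]; s2 += w * x[i] * x[i];
    }
    double det = s0 * s2 - s1 * s1;
    if (pinned || det <= 0 || !R_finite(det)) { out[j] = 0.0; continue; }
    i11 = s0 / det;
    out[j] = std::fabs(b1) / std::sqrt(i11);
  }
  return out;
}
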