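#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Inverse-Gaussian draw, Michael/Schucany/Haas transformation.
// Uses R's RNG stream so results are reproducible under set.seed().
static double rinvgauss1(double mu, double shape) {
  double nu = norm_rand();
  double z = nu * nu;
  double x = mu + (mu * mu * z) / (2.0 * shape) -
    (mu / (2.0 * shape)) * std::sqrt(4.0 * mu * shape * z + mu * mu * z * z);
  if (!(x > 0.0) || !std::isfinite(x)) {
    // catastrophic cancellation for extreme mu*z/shape: the transformed
    // root is then numerically 0 and the acceptance step selects mu^2/x
    x = mu * 1e-14;
  }
  double u = unif_rand();
  return (u <= mu / (mu + x)) ? x : (mu * mu / x);
}

// [[Rcpp::export]]
NumericVector rinvgauss_cpp(int n, NumericVector mu, NumericVector shape) {
  NumericVector out(n);
  GetRNGstate();
  for (int i = 0; i < n; ++i) {
    double m = mu[i % mu.size()], s = shape[i % shape.size()];
    if (!(m > 0.0) || !(s > 0.0))
      stop("rinvgauss: mean and shape must be positive");
    out[i] = rinvgauss1(m, s);
  }
  PutRNGstate();
  return out;
}

// Gibbs sampler for the Bayesian LASSO / ridge hierarchy:
//   y | mu, beta, sigma2        ~ N(mu 1 + X beta, sigma2 I)
//   lasso: beta_j | sigma2, tau2_j ~ N(0, sigma2 tau2_j),
//          tau2_j ~ Exp(rate lambda^2 / 2)  (scale mixture of the
//          conditional Laplace prior with rate lambda / sigma)
//   ridge: beta   | sigma2, lambda ~ N(0, sigma2 / lambda I)
//   p(sigma2) ∝ 1/sigma2, flat prior on mu
//   random tuning parameter: p(lambda) ∝ 1/lambda, giving
//     lasso: lambda^2 | tau2 ~ Gamma(m, rate sum(tau2)/2)
//     ridge: lambda | beta, sigma2 ~ Gamma(m/2, rate sum(beta^2)/(2 sigma2))
//
// [[Rcpp::export]]
List gibbs_shrinkage_cpp(NumericMatrix X, NumericVector y, double lambda_init,
                         bool lambda_random, int burn_in, int thin,
                         int n_draws, bool ridge, bool keep_tau2,
                         bool sample_mu) {
  const int n = X.nrow(), m = X.ncol();
  const double *xp = X.begin();

  std::vector<double> beta(m, 0.0), invtau2(m, 1.0), xtx(m), r(n);
  double mu = 0.0, sigma2 = 1.0, lambda = lambda_init;

  // column squared norms (entries may be -1/0/+1 or arbitrary reals)
  for (int j = 0; j < m; ++j) {
    const double *xj = xp + (size_t)j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xtx[j] = s;
  }

  // initial state: beta = 0, mu = mean(y), sigma2 = var(y)
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  mu = sample_mu ? ybar : 0.0;
  double v = 0.0;
  for (int i = 0; i < n; ++i) v += (y[i] - ybar) * (y[i] - ybar);
  sigma2 = (n > 1) ? v / (n - 1) : 1.0;
  if (!(sigma2 > 0.0)) sigma2 = 1.0;
  for (int i = 0; i < n; ++i) r[i] = y[i] - mu;

  NumericMatrix beta_out(n_draws, m);
  NumericVector mu_out(n_draws), sigma2_out(n_draws);
  NumericMatrix tau2_out = keep_tau2 ? NumericMatrix(n_draws, m)
                                     : NumericMatrix(0, 0);
  NumericVector lam_out = lambda_random ? NumericVector(n_draws)
                                        : NumericVector(0);

  const int total = burn_in + thin * n_draws;
  int kept = 0;
  GetRNGstate();
  for (int it = 1; it <= total; ++it) {
    // --- beta, one coordinate at a time ---
    for (int j = 0; j < m; ++j) {
      const double *xj = xp + (size_t)j * n;
      double dot = 0.0;
      for (int i = 0; i < n; ++i) dot += xj[i] * r[i];
      dot += xtx[j] * beta[j];                 // x_j' (r with beta_j added back)
      const double prior_prec = ridge ? lambda : invtau2[j];
      const double prec = xtx[j] + prior_prec;
      const double bmean = dot / prec;
      const double bnew = bmean + norm_rand() * std::sqrt(sigma2 / prec);
      if (!std::isfinite(bnew)) {
        PutRNGstate();
        stop("sampler error at iteration %d: non-finite draw for beta[%d]",
             it, j + 1);
      }
      const double delta = bnew - beta[j];
      if (delta != 0.0)
        for (int i = 0; i < n; ++i) r[i] -= xj[i] * delta;
      beta[j] = bnew;
    }

    // --- mu, flat prior ---
    if (sample_mu) {
      double rbar = 0.0;
      for (int i = 0; i < n; ++i) rbar += r[i];
      rbar /= n;
      const double mu_new = (mu + rbar) + norm_rand() * std::sqrt(sigma2 / n);
      const double dmu = mu_new - mu;
      for (int i = 0; i < n; ++i) r[i] -= dmu;
      mu = mu_new;
    }

    // --- sigma2, inverse-gamma ---
    double rss = 0.0;
    for (int i = 0; i < n; ++i) rss += r[i] * r[i];
    double pen = 0.0;
    if (ridge) {
      double bb = 0.0;
      for (int j = 0; j < m; ++j) bb += beta[j] * beta[j];
      pen = lambda * bb;
    } else {
      for (int j = 0; j < m; ++j) pen += beta[j] * beta[j] * invtau2[j];
    }
    const double shape = 0.5 * (n + m);
    const double rate = 0.5 * (rss + pen);
    sigma2 = 1.0 / R::rgamma(shape, 1.0 / std::max(rate, 1e-300));
    if (!std::isfinite(sigma2) || !(sigma2 > 0.0)) {
      PutRNGstate();
      stop("sampler error at iteration %d: degenerate draw for sigma2", it);
    }

    // --- tau2 (lasso only), via inverse-Gaussian for 1/tau2_j ---
    if (!ridge) {
      const double sig = std::sqrt(sigma2);
      for (int j = 0; j < m; ++j) {
        const double ab = std::max(std::fabs(beta[j]), 1e-10);
        invtau2[j] = rinvgauss1(lambda * sig / ab, lambda * lambda);
        if (!std::isfinite(invtau2[j]) || !(invtau2[j] > 0.0)) {
          PutRNGstate();
          stop("sampler error at iteration %d: degenerate draw for tau2[%d]",
               it, j + 1);
        }
      }
    }

    // --- lambda, when random ---
    if (lambda_random) {
      if (ridge) {
        double bb = 0.0;
        for (int j = 0; j < m; ++j) bb += beta[j] * beta[j];
        const double rate_l = std::max(0.5 * bb / sigma2, 1e-300);
        lambda = R::rgamma(0.5 * m, 1.0 / rate_l);
      } else {
        double st = 0.0;
        for (int j = 0; j < m; ++j) st += 1.0 / invtau2[j];
        const double lam2 = R::rgamma((double)m, 1.0 / std::max(0.5 * st, 1e-300));
        lambda = std::sqrt(lam2);
      }
      if (!std::isfinite(lambda) || !(lambda > 0.0)) {
        PutRNGstate();
        stop("sampler error at iteration %d: degenerate draw for lambda", it);
      }
    }

    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int j = 0; j < m; ++j) beta_out(kept, j) = beta[j];
      mu_out[kept] = mu;
      sigma2_out[kept] = sigma2;
      if (keep_tau2 && !ridge)
        for (int j = 0; j < m; ++j) tau2_out(kept, j) = 1.0 / invtau2[j];
      if (lambda_random) lam_out[kept] = lambda;
      ++kept;
    }
    if ((it & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();

  List out = List::create(_["beta"] = beta_out, _["mu"] = mu_out,
                          _["sigma2"] = sigma2_out);
  if (keep_tau2 && !ridge) out["tau2"] = tau2_out;
  if (lambda_random) out["lambda"] = lam_out;
  return out;
}
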