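// Single-site Gibbs samplers for whole-genome regression.
// Uses R's RNG (seed with set.seed() before calling).

#include <Rcpp.h>
using namespace Rcpp;

static inline double rinvchisq(double df, double scale) {
  // scaled inverse chi-square draw
  return df * scale / R::rchisq(df);
}

// Spike-and-slab with scaled-t slab, implemented as marker-specific
// scaled-inverse-chi-square variances. Fixed slab probability pi_slab.
// [[Rcpp::export]]
List bayesB_gibbs(NumericVector y, NumericMatrix X,
                  Nullable<NumericVector> W_, int n_iter, int burn_in,
                  int thin, double pi_slab, double df_slab,
                  double scale_slab, double df_e, double scale_e) {
  int n = y.size(), m = X.ncol();
  bool has_w = W_.isNotNull();
  NumericVector W = has_w ? NumericVector(W_) : NumericVector(0);

  std::vector<double> xtx(m), wty;
  for (int j = 0; j < m; ++j) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  double wtw = 0;
  if (has_w) for (int i = 0; i < n; ++i) wtw += W[i] * W[i];

  double mu = mean(y), beta = 0, sigma_e2 = scale_e;
  std::vector<double> gamma(m, 0.0), sj2(m, scale_slab);
  std::vector<int> delta(m, 0);
  NumericVector e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  // posterior accumulators
  double mu_acc = 0, beta_acc = 0, se_acc = 0, gv_acc = 0;
  std::vector<double> g_acc(m, 0.0), pip_acc(m, 0.0);
  int n_samp = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // intercept (flat prior)
    double ebar = 0;
    for (int i = 0; i < n; ++i) ebar += e[i] + mu;
    ebar /= n;
    double mu_new = R::rnorm(ebar, std::sqrt(sigma_e2 / n));
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;
    // covariate effect (flat prior)
    if (has_w && wtw > 0) {
      double r = 0;
      for (int i = 0; i < n; ++i) r += W[i] * (e[i] + W[i] * beta);
      double bhat = r / wtw;
      double beta_new = R::rnorm(bhat, std::sqrt(sigma_e2 / wtw));
      for (int i = 0; i < n; ++i) e[i] += W[i] * (beta - beta_new);
      beta = beta_new;
    }
    // markers
    for (int j = 0; j < m; ++j) {
      double c = xtx[j];
      if (c <= 0) { delta[j] = 0; gamma[j] = 0.0; continue; }
      double r = 0;
      for (int i = 0; i < n; ++i) r += X(i, j) * e[i];
      r += c * gamma[j];  // residual with marker j put back
      double v = sj2[j];
      double log_bf = 0.5 * r * r * v / (sigma_e2 * (c * v + sigma_e2)) -
                      0.5 * std::log(c * v / sigma_e2 + 1.0);
      double p1 = pi_slab;
      if (p1 > 0 && p1 < 1) {
        double lo = std::log(p1) - std::log(1 - p1) + log_bf;
        p1 = 1.0 / (1.0 + std::exp(-lo));
      } else if (p1 >= 1) p1 = 1.0;
      int dnew = (R::unif_rand() < p1) ? 1 : 0;
      double gnew = 0.0;
      if (dnew == 1) {
        double prec = c / sigma_e2 + 1.0 / v;
        double mean_g = (r / sigma_e2) / prec;
        gnew = R::rnorm(mean_g, std::sqrt(1.0 / prec));
      }
      if (gnew != gamma[j]) {
        double dgam = gamma[j] - gnew;
        for (int i = 0; i < n; ++i) e[i] += X(i, j) * dgam;
      }
      gamma[j] = gnew;
      delta[j] = dnew;
      // marker variance: posterior draw if in the slab, prior draw otherwise
      if (dnew == 1)
        sj2[j] = rinvchisq(df_slab + 1.0,
                           (gnew * gnew + df_slab * scale_slab) / (df_slab + 1.0));
      else
        sj2[j] = rinvchisq(df_slab, scale_slab);
    }
    // residual variance
    double sse = 0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma_e2 = rinvchisq(df_e + n, (sse + df_e * scale_e) / (df_e + n));

    if (it > burn_in && ((it - burn_in) % thin == 0)) {
      ++n_samp;
      mu_acc += mu; beta_acc += beta; se_acc += sigma_e2;
      double gv = 0;
      for (int j = 0; j < m; ++j) {
        g_acc[j] += gamma[j];
        pip_acc[j] += delta[j];
        gv += gamma[j] * gamma[j] * xtx[j] / n;
      }
      gv_acc += gv;
    }
  }
  if (n_samp == 0) stop("no posterior samples; check iteration settings");
  NumericVector gpost(m), pip(m);
  for (int j = 0; j < m; ++j) {
    gpost[j] = g_acc[j] / n_samp;
    pip[j] = pip_acc[j] / n_samp;
  }
  return List::create(_["mu"] = mu_acc / n_samp, _["beta"] = beta_acc / n_samp,
                      _["gamma"] = gpost, _["pip"] = pip,
                      _["sigma_e2"] = se_acc / n_samp,
                      _["genetic_var"] = gv_acc / n_samp,
                      _["n_samples"] = n_samp);
}

// Four-component normal mixture on marker effects with component variances
// cvar * sigma_g2 (first component is the point mass at zero), Dirichlet
// update on the mixture proportions, sigma_g2 updated each sweep.
// [[Rcpp::export]]
List bayesR_gibbs(NumericVector y, NumericMatrix X,
                  Nullable<NumericVector> W_, int n_iter, int burn_in,
                  int thin, NumericVector cvar, NumericVector pi_init,
                  bool update_pi, double sigma_g2_init, double df_g,
                  double df_e, double scale_e) {
  int n = y.size(), m = X.ncol(), K = cvar.size();
  bool has_w = W_.isNotNull();
  NumericVector W = has_w ? NumericVector(W_) : NumericVector(0);

  std::vector<double> xtx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }
  double wtw = 0;
  if (has_w) for (int i = 0; i < n; ++i) wtw += W[i] * W[i];

  double mu = mean(y), beta = 0, sigma_e2 = scale_e;
  double sigma_g2 = sigma_g2_init;
  std::vector<double> gamma(m, 0.0), pi(K);
  std::vector<int> comp(m, 0);
  for (int k = 0; k < K; ++k) pi[k] = pi_init[k];
  NumericVector e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  double mu_acc = 0, beta_acc = 0, se_acc = 0, sg_acc = 0;
  std::vector<double> g_acc(m, 0.0), pi_acc(K, 0.0);
  std::vector<double> logL(K), prob(K);
  int n_samp = 0;

  for (int it = 1; it <= n_iter; ++it) {
    double ebar = 0;
    for (int i = 0; i < n; ++i) ebar += e[i] + mu;
    ebar /= n;
    double mu_new = R::rnorm(ebar, std::sqrt(sigma_e2 / n));
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;
    if (has_w && wtw > 0) {
      double r = 0;
      for (int i = 0; i < n; ++i) r += W[i] * (e[i] + W[i] * beta);
      double bhat = r / wtw;
      double beta_new = R::rnorm(bhat, std::sqrt(sigma_e2 / wtw));
      for (int i = 0; i < n; ++i) e[i] += W[i] * (beta - beta_new);
      beta = beta_new;
    }
    std::vector<int> counts(K, 0);
    double qform = 0; int m_nonzero = 0;
    for (int j = 0; j < m; ++j) {
      double c = xtx[j];
      if (c <= 0) { comp[j] = 0; gamma[j] = 0.0; counts[0]++; continue; }
      double r = 0;
      for (int i = 0; i < n; ++i) r += X(i, j) * e[i];
      r += c * gamma[j];
      double lmax = -INFINITY;
      for (int k = 0; k < K; ++k) {
        double v = cvar[k] * sigma_g2;
        double l = (pi[k] <= 0) ? -INFINITY : std::log(pi[k]);
        if (v > 0 && std::isfinite(l))
          l += 0.5 * r * r * v / (sigma_e2 * (c * v + sigma_e2)) -
               0.5 * std::log(c * v / sigma_e2 + 1.0);
        logL[k] = l;
        if (l > lmax) lmax = l;
      }
      double tot = 0;
      for (int k = 0; k < K; ++k) {
        prob[k] = std::isfinite(logL[k]) ? std::exp(logL[k] - lmax) : 0.0;
        tot += prob[k];
      }
      double u = R::unif_rand() * tot, acc = 0;
      int knew = 0;
      for (int k = 0; k < K; ++k) { acc += prob[k]; if (u <= acc) { knew = k; break; } }
      double gnew = 0.0;
      double v = cvar[knew] * sigma_g2;
      if (v > 0) {
        double prec = c / sigma_e2 + 1.0 / v;
        gnew = R::rnorm((r / sigma_e2) / prec, std::sqrt(1.0 / prec));
      }
      if (gnew != gamma[j]) {
        double dgam = gamma[j] - gnew;
        for (int i = 0; i < n; ++i) e[i] += X(i, j) * dgam;
      }
      gamma[j] = gnew;
      comp[j] = knew;
      counts[knew]++;
      if (v > 0) { qform += gnew * gnew / cvar[knew]; m_nonzero++; }
    }
    // mixture proportions: Dirichlet(1 + counts)
    if (update_pi) {
      double tot = 0;
      for (int k = 0; k < K; ++k) { pi[k] = R::rgamma(1.0 + counts[k], 1.0); tot += pi[k]; }
      for (int k = 0; k < K; ++k) pi[k] /= tot;
    }
    // genetic variance scalar
    if (m_nonzero > 0)
      sigma_g2 = rinvchisq(df_g + m_nonzero,
                           (qform + df_g * sigma_g2_init) / (df_g + m_nonzero));
    else
      sigma_g2 = rinvchisq(df_g, sigma_g2_init);
    double sse = 0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma_e2 = rinvchisq(df_e + n, (sse + df_e * scale_e) / (df_e + n));

    if (it > burn_in && ((it - burn_in) % thin == 0)) {
      ++n_samp;
      mu_acc += mu; beta_acc += beta; se_acc += sigma_e2; sg_acc += sigma_g2;
      for (int j = 0; j < m; ++j) g_acc[j] += gamma[j];
      for (int k = 0; k < K; ++k) pi_acc[k] += pi[k];
    }
  }
  if (n_samp == 0) stop("no posterior samples; check iteration settings");
  NumericVector gpost(m), pipost(K);
  for (int j = 0; j < m; ++j) gpost[j] = g_acc[j] / n_samp;
  for (int k = 0; k < K; ++k) pipost[k] = pi_acc[k] / n_samp;
  return List::create(_["mu"] = mu_acc / n_samp, _["beta"] = beta_acc / n_samp,
                      _["gamma"] = gpost, _["pi"] = pipost,
                      _["sigma_e2"] = se_acc / n_samp,
                      _["sigma_g2"] = sg_acc / n_samp,
                      _["n_samples"] = n_samp);
}
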