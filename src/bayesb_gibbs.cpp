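// Single-site Gibbs sampler for the Bayes B mixture model with fixed
// (contemporary group, age, haplotype-allele) effects and genome-wide SNP
// effects under a pi-mixture prior, for a Gaussian trait or a binary trait
// via latent liabilities (threshold at 0, residual variance fixed at 1).
// Uses R's RNG so chains are exactly reproducible from set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double rinvchisq(double nu, double scale) {
  return nu * scale / R::rchisq(nu);
}

// [[Rcpp::export]]
List bayesb_gibbs(NumericVector y_init, IntegerVector ybin, bool binary,
                  NumericMatrix W, NumericMatrix X,
                  double pi_null, int chain_length, int burn_in, int thin,
                  double nu_s, double scale_s, double nu_e, double scale_e,
                  bool keep_liab) {
  const int n = W.nrow();
  const int q = W.ncol();
  const int p = X.ncol();
  const int nret = (chain_length - burn_in) / thin;

  std::vector<double> l(n), e(n), b(q, 0.0), s(p, 0.0), sig2j(p, scale_s);
  for (int i = 0; i < n; ++i) { l[i] = y_init[i]; e[i] = l[i]; }
  double sige2 = binary ? 1.0 : scale_e;

  std::vector<double> wtw(q, 0.0), xtx(p, 0.0);
  for (int k = 0; k < q; ++k)
    for (int i = 0; i < n; ++i) wtw[k] += W(i, k) * W(i, k);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) xtx[j] += X(i, j) * X(i, j);

  NumericMatrix fixed_draws(nret, q), snp_draws(nret, p);
  NumericVector sige_draws(nret), delta_mean(p);
  NumericMatrix liab_draws(keep_liab ? nret : 1, keep_liab ? n : 1);

  const double log_prior_odds0 = std::log(pi_null) - std::log(1.0 - pi_null);
  int r = 0;

  for (int t = 1; t <= chain_length; ++t) {
    // --- fixed effects, flat prior -----------------------------------
    for (int k = 0; k < q; ++k) {
      const double wk2 = wtw[k];
      if (wk2 <= 0.0) continue;
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += W(i, k) * e[i];
      rhs += wk2 * b[k];
      const double bnew = R::rnorm(rhs / wk2, std::sqrt(sige2 / wk2));
      const double diff = b[k] - bnew;
      if (diff != 0.0)
        for (int i = 0; i < n; ++i) e[i] += W(i, k) * diff;
      b[k] = bnew;
    }

    // --- SNP effects under the mixture prior --------------------------
    for (int j = 0; j < p; ++j) {
      const double xx = xtx[j];
      const double sold = s[j];
      if (xx <= 0.0) {
        s[j] = 0.0;
        sig2j[j] = rinvchisq(nu_s, scale_s);
        continue;
      }
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      rhs += xx * sold;

      const double v0 = xx * sige2;
      const double v1 = xx * xx * sig2j[j] + xx * sige2;
      const double logBF = 0.5 * (std::log(v0) - std::log(v1)) +
        0.5 * rhs * rhs * (1.0 / v0 - 1.0 / v1);
      const double log_odds0 = log_prior_odds0 - logBF;
      double p1;
      if (log_odds0 > 35.0) p1 = 0.0;
      else if (log_odds0 < -35.0) p1 = 1.0;
      else p1 = 1.0 / (1.0 + std::exp(log_odds0));

      double snew = 0.0;
      int del = 0;
      if (R::unif_rand() < p1) {
        del = 1;
        const double denom = xx + sige2 / sig2j[j];
        snew = R::rnorm(rhs / denom, std::sqrt(sige2 / denom));
      }
      const double diff = sold - snew;
      if (diff != 0.0)
        for (int i = 0; i < n; ++i) e[i] += X(i, j) * diff;
      s[j] = snew;

      // locus variance: conjugate update when in the model, prior draw
      // otherwise
      if (del)
        sig2j[j] = rinvchisq(nu_s + 1.0,
                             (nu_s * scale_s + snew * snew) / (nu_s + 1.0));
      else
        sig2j[j] = rinvchisq(nu_s, scale_s);

      if (t > burn_in) delta_mean[j] += del;
    }

    // --- residual variance / latent liabilities -----------------------
    if (!binary) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      sige2 = (sse + nu_e * scale_e) / R::rchisq(nu_e + n);
    } else {
      for (int i = 0; i < n; ++i) {
        const double mu = l[i] - e[i];
        const double plo = R::pnorm(0.0, mu, 1.0, 1, 0);
        double u;
        if (ybin[i] == 1) u = plo + R::unif_rand() * (1.0 - plo);
        else              u = R::unif_rand() * plo;
        if (u < 1e-12) u = 1e-12;
        if (u > 1.0 - 1e-12) u = 1.0 - 1e-12;
        double lnew = R::qnorm(u, mu, 1.0, 1, 0);
        if (ybin[i] == 1 && lnew <= 0.0) lnew = 1e-10;
        if (ybin[i] == 0 && lnew > 0.0) lnew = -1e-10;
        e[i] = lnew - mu;
        l[i] = lnew;
      }
    }

    // --- retain --------------------------------------------------------
    if (t > burn_in && (t - burn_in) % thin == 0 && r < nret) {
      for (int k = 0; k < q; ++k) fixed_draws(r, k) = b[k];
      for (int j = 0; j < p; ++j) snp_draws(r, j) = s[j];
      sige_draws[r] = sige2;
      if (keep_liab)
        for (int i = 0; i < n; ++i) liab_draws(r, i) = l[i];
      ++r;
    }
  }

  const double post_iters = chain_length - burn_in;
  for (int j = 0; j < p; ++j) delta_mean[j] /= post_iters;

  return List::create(_["fixed"] = fixed_draws, _["snp"] = snp_draws,
                      _["sigma_e"] = sige_draws, _["delta_mean"] = delta_mean,
                      _["liab"] = liab_draws, _["n_retained"] = nret);
}
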