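#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for a finite Bayesian mixture of Gaussians over
// gene expression profiles. Genes are data points in sample space; each
// cluster has per-sample means/precisions with a conjugate normal-gamma
// prior (mu0, kappa0, a0, b0) and a symmetric Dirichlet(alpha/K) prior on
// mixture weights. Uses R's RNG so set.seed() controls the draw.

// Per-sample part of the Student-t predictive log-density; the df-dependent
// normalizing constant is hoisted into the caller (it only depends on the
// cluster size, not the sample).
static inline double log_t_pred_sample(double x, double n, double sum,
                                       double sumsq, double mu0,
                                       double kappa0, double a0, double b0,
                                       double df) {
  double kappa_n = kappa0 + n;
  double mu_n, b_n;
  if (n > 0) {
    double mean = sum / n;
    double ss = sumsq - sum * sum / n;
    if (ss < 0) ss = 0;
    mu_n = (kappa0 * mu0 + sum) / kappa_n;
    b_n = b0 + 0.5 * ss + kappa0 * n * (mean - mu0) * (mean - mu0) /
          (2.0 * kappa_n);
  } else {
    mu_n = mu0;
    b_n = b0;
  }
  double a_n = df / 2.0;
  double scale2 = b_n * (kappa_n + 1.0) / (a_n * kappa_n);
  double z2 = (x - mu_n) * (x - mu_n) / (df * scale2);
  return -0.5 * std::log(scale2) - (df + 1.0) / 2.0 * std::log1p(z2);
}

// [[Rcpp::export]]
IntegerVector gibbs_mixture_cpp(NumericMatrix x, int K, double alpha,
                                double mu0, double kappa0, double a0,
                                double b0, int n_sweeps) {
  int G = x.nrow(), S = x.ncol();
  RNGScope scope;

  std::vector<int> z(G);
  std::vector<double> nk(K, 0.0);
  std::vector<std::vector<double> > sum(K, std::vector<double>(S, 0.0));
  std::vector<std::vector<double> > sumsq(K, std::vector<double>(S, 0.0));

  for (int g = 0; g < G; ++g) {
    int k = (int)std::floor(unif_rand() * K);
    if (k == K) k = K - 1;
    z[g] = k;
    nk[k] += 1.0;
    for (int s = 0; s < S; ++s) {
      sum[k][s] += x(g, s);
      sumsq[k][s] += x(g, s) * x(g, s);
    }
  }

  std::vector<double> logp(K);
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int g = 0; g < G; ++g) {
      int k_old = z[g];
      nk[k_old] -= 1.0;
      for (int s = 0; s < S; ++s) {
        sum[k_old][s] -= x(g, s);
        sumsq[k_old][s] -= x(g, s) * x(g, s);
      }

      double maxlp = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double df = 2.0 * (a0 + nk[k] / 2.0);
        double c_df = R::lgammafn((df + 1.0) / 2.0) -
                      R::lgammafn(df / 2.0) - 0.5 * std::log(df * M_PI);
        double lp = std::log(nk[k] + alpha / K) + S * c_df;
        for (int s = 0; s < S; ++s) {
          lp += log_t_pred_sample(x(g, s), nk[k], sum[k][s], sumsq[k][s],
                                  mu0, kappa0, a0, b0, df);
        }
        logp[k] = lp;
        if (lp > maxlp) maxlp = lp;
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        logp[k] = std::exp(logp[k] - maxlp);
        tot += logp[k];
      }
      double u = unif_rand() * tot, acc = 0.0;
      int k_new = K - 1;
      for (int k = 0; k < K; ++k) {
        acc += logp[k];
        if (u <= acc) { k_new = k; break; }
      }

      z[g] = k_new;
      nk[k_new] += 1.0;
      for (int s = 0; s < S; ++s) {
        sum[k_new][s] += x(g, s);
        sumsq[k_new][s] += x(g, s) * x(g, s);
      }
    }
  }

  IntegerVector out(G);
  for (int g = 0; g < G; ++g) out[g] = z[g] + 1;
  return out;
}
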