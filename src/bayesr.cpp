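#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gibbs sampler for the four-component normal-mixture whole-genome
// regression: y = mu + Z b + e, b_i | c_i = k ~ N(0, gamma_k * sigma_g2),
// P(c_i = k) = pi_k, gamma_1 = 0 (point mass at zero). Conjugate updates
// throughout with running-residual bookkeeping; mixture proportions from a
// symmetric Dirichlet(1,1,1,1), variance components from scaled inverse
// chi-square conditionals. Uses R's RNG so set.seed() governs the chain.
//
// Z must be column-standardized (mean 0); y on its raw scale.
// [[Rcpp::export(name = ".bayesr_gibbs")]]
List bayesr_gibbs(NumericMatrix Z, NumericVector y, NumericVector gamma,
                  NumericVector pi_init, int iterations, int burn_in,
                  int thin, bool update_pi, bool update_sigma,
                  double sigma_g2_init, double sigma_e2_init,
                  IntegerVector fixed_comp, double df0_g, double s0_g,
                  NumericVector dirichlet_alpha, bool keep_effects) {
  const int n = Z.nrow(), m = Z.ncol(), K = gamma.size();
  std::vector<double> ztz(m);
  for (int j = 0; j < m; ++j) {
    double s = 0;
    const double *zj = &Z(0, j);
    for (int i = 0; i < n; ++i) s += zj[i] * zj[i];
    ztz[j] = s;
  }
  std::vector<double> b(m, 0.0);
  std::vector<int> comp(m, 0);
  double mu = mean(y);
  double sigma_g2 = sigma_g2_init, sigma_e2 = sigma_e2_init;
  std::vector<double> pi(K);
  for (int k = 0; k < K; ++k) pi[k] = pi_init[k];
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i] - mu;

  std::vector<double> b_sum(m, 0.0), pip_sum(m * K, 0.0);
  double mu_sum = 0;
  int n_kept = 0;
  int n_log = 0;
  for (int it = burn_in; it < iterations; ++it)
    if ((it - burn_in) % thin == 0) ++n_log;
  NumericMatrix chain(n_log, 3 + K); // sigma_g2 sigma_e2 model_size pi1..piK
  NumericMatrix b_draws(keep_effects ? n_log : 0, keep_effects ? m : 0);
  int log_row = 0;
  std::vector<double> logl(K), cband(K);

  RNGScope scope;
  for (int it = 0; it < iterations; ++it) {
    // intercept
    double rsum = 0;
    for (int i = 0; i < n; ++i) rsum += r[i] + mu;
    double mu_new = R::rnorm(rsum / n, std::sqrt(sigma_e2 / n));
    for (int i = 0; i < n; ++i) r[i] += mu - mu_new;
    mu = mu_new;

    // per-SNP component indicator and effect
    int m_nn = 0;
    double ssb = 0; // sum b^2/gamma over non-null
    for (int j = 0; j < m; ++j) {
      const double *zj = &Z(0, j);
      double rhs = 0;
      for (int i = 0; i < n; ++i) rhs += zj[i] * r[i];
      rhs += ztz[j] * b[j];
      int c;
      if (fixed_comp[j] >= 0) {
        c = fixed_comp[j];
      } else {
        double lmax = -INFINITY;
        for (int k = 0; k < K; ++k) {
          if (pi[k] <= 0) { logl[k] = -INFINITY; continue; }
          if (gamma[k] == 0) {
            logl[k] = std::log(pi[k]);
          } else {
            double vk = gamma[k] * sigma_g2;
            double C = ztz[j] + sigma_e2 / vk;
            cband[k] = C;
            logl[k] = std::log(pi[k]) +
              0.5 * (std::log(sigma_e2) - std::log(vk) - std::log(C)) +
              rhs * rhs / (2.0 * sigma_e2 * C);
          }
          if (logl[k] > lmax) lmax = logl[k];
        }
        double tot = 0;
        for (int k = 0; k < K; ++k) {
          logl[k] = std::exp(logl[k] - lmax);
          tot += logl[k];
        }
        double u = R::unif_rand() * tot, acc = 0;
        c = K - 1;
        for (int k = 0; k < K; ++k) {
          acc += logl[k];
          if (u <= acc) { c = k; break; }
        }
      }
      double b_new = 0;
      if (gamma[c] > 0) {
        double vk = gamma[c] * sigma_g2;
        double C = ztz[j] + sigma_e2 / vk;
        b_new = R::rnorm(rhs / C, std::sqrt(sigma_e2 / C));
        ++m_nn;
        ssb += b_new * b_new / gamma[c];
      }
      double diff = b_new - b[j];
      if (diff != 0) for (int i = 0; i < n; ++i) r[i] -= zj[i] * diff;
      b[j] = b_new;
      comp[j] = c;
    }

    if (update_sigma) {
      double df = df0_g + m_nn;
      sigma_g2 = (ssb + df0_g * s0_g) / R::rchisq(df);
      double sse = 0;
      for (int i = 0; i < n; ++i) sse += r[i] * r[i];
      sigma_e2 = sse / R::rchisq((double)(n - 2));
    }
    if (update_pi) {
      std::vector<double> cnt(K);
      for (int k = 0; k < K; ++k) cnt[k] = dirichlet_alpha[k];
      for (int j = 0; j < m; ++j) cnt[comp[j]] += 1.0;
      double tot = 0;
      for (int k = 0; k < K; ++k) { pi[k] = R::rgamma(cnt[k], 1.0); tot += pi[k]; }
      for (int k = 0; k < K; ++k) pi[k] /= tot;
    }

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      ++n_kept;
      mu_sum += mu;
      int m_nn_now = 0;
      for (int j = 0; j < m; ++j) {
        b_sum[j] += b[j];
        pip_sum[j * K + comp[j]] += 1.0;
        if (comp[j] > 0) ++m_nn_now;
        if (keep_effects) b_draws(log_row, j) = b[j];
      }
      chain(log_row, 0) = sigma_g2;
      chain(log_row, 1) = sigma_e2;
      chain(log_row, 2) = m_nn_now;
      for (int k = 0; k < K; ++k) chain(log_row, 3 + k) = pi[k];
      ++log_row;
    }
  }

  NumericVector b_mean(m);
  NumericMatrix pip(m, K);
  for (int j = 0; j < m; ++j) {
    b_mean[j] = b_sum[j] / n_kept;
    for (int k = 0; k < K; ++k) pip(j, k) = pip_sum[j * K + k] / n_kept;
  }
  return List::create(_["b_mean"] = b_mean, _["mu_mean"] = mu_sum / n_kept,
                      _["pip"] = pip, _["chain"] = chain,
                      _["n_kept"] = n_kept, _["b_draws"] = b_draws);
}
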