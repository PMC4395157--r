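// Random-walk Metropolis sampler for a hierarchical Bayesian F_ST model.
//
// Observed allele-1 counts a_ij (locus i, population j, haploid sample
// size n_ij) follow a beta-binomial whose mean is the ancestral frequency
// pi_i and whose overdispersion is governed by a logistic decomposition of
// the locus/population F_ST:
//
//   F_ij   = logistic(alpha_i + beta_j)
//   theta_ij = (1 - F_ij) / F_ij = exp(-(alpha_i + beta_j))
//   a_ij ~ BetaBinomial(n_ij, pi_i * theta_ij, (1 - pi_i) * theta_ij)
//
// Priors: alpha_i ~ N(0,1), beta_j ~ N(-1,1), pi_i ~ Uniform(0,1)
// (clamped away from the boundary).  Proposal scales are tuned during
// pilot runs toward a 25-45% acceptance rate.  Uses R's RNG, so results
// are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static const double PI_LO = 1e-6, PI_HI = 1.0 - 1e-6;

// log beta-binomial kernel without the binomial coefficient (constant in
// the parameters, so it cancels in every Metropolis ratio)
static inline double lbetabin(double a, double n, double x, double y) {
  return R::lbeta(a + x, n - a + y) - R::lbeta(x, y);
}

static inline double loglik_cell(double a, double n, double pi_i,
                                 double s /* alpha_i + beta_j */) {
  double th = std::exp(-s);
  return lbetabin(a, n, pi_i * th, (1.0 - pi_i) * th);
}

// [[Rcpp::export(name = ".outlier_mcmc_cpp")]]
List outlier_mcmc_cpp(NumericMatrix A, NumericMatrix N,
                      int pilot_runs, int pilot_length,
                      int burn_in, int samples, int thin) {
  const int L = A.nrow(), J = A.ncol();

  std::vector<double> alpha(L, 0.0), pi(L), beta(J, -1.0);
  std::vector<double> s_alpha(L, 0.5), s_pi(L, 0.1), s_beta(J, 0.3);

  // initialize pi at pooled frequency
  for (int i = 0; i < L; ++i) {
    double tot = 0, cnt = 0;
    for (int j = 0; j < J; ++j) { tot += A(i, j); cnt += N(i, j); }
    double p = cnt > 0 ? tot / cnt : 0.5;
    pi[i] = std::min(PI_HI, std::max(PI_LO, p));
  }

  // cached per-cell log-likelihood
  NumericMatrix ll(L, J);
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < J; ++j) {
      ll(i, j) = loglik_cell(A(i, j), N(i, j), pi[i], alpha[i] + beta[j]);
      if (!R_finite(ll(i, j)))
        stop("non-finite likelihood at locus %d, population %d", i + 1, j + 1);
    }

  std::vector<long> try_a(L, 0), acc_a(L, 0), try_p(L, 0), acc_p(L, 0);
  std::vector<long> try_b(J, 0), acc_b(J, 0);
  std::vector<double> row_new(J);

  NumericVector score(L, 0.0), alpha_mean(L, 0.0);
  std::vector<double> beta_mean(J, 0.0);
  int recorded = 0;

  auto sweep = [&](bool record_counts) {
    // alpha_i updates
    for (int i = 0; i < L; ++i) {
      double prop = alpha[i] + R::norm_rand() * s_alpha[i];
      double d = 0.0;
      for (int j = 0; j < J; ++j) {
        row_new[j] = loglik_cell(A(i, j), N(i, j), pi[i], prop + beta[j]);
        d += row_new[j] - ll(i, j);
      }
      d += -0.5 * (prop * prop - alpha[i] * alpha[i]);   // N(0,1) prior
      if (record_counts) ++try_a[i];
      if (R_finite(d) && (d >= 0.0 || R::unif_rand() < std::exp(d))) {
        alpha[i] = prop;
        for (int j = 0; j < J; ++j) ll(i, j) = row_new[j];
        if (record_counts) ++acc_a[i];
      }
    }
    // pi_i updates (uniform prior; reject proposals outside the clamp)
    for (int i = 0; i < L; ++i) {
      double prop = pi[i] + R::norm_rand() * s_pi[i];
      if (record_counts) ++try_p[i];
      if (prop <= PI_LO || prop >= PI_HI) continue;
      double d = 0.0;
      for (int j = 0; j < J; ++j) {
        row_new[j] = loglik_cell(A(i, j), N(i, j), prop, alpha[i] + beta[j]);
        d += row_new[j] - ll(i, j);
      }
      if (R_finite(d) && (d >= 0.0 || R::unif_rand() < std::exp(d))) {
        pi[i] = prop;
        for (int j = 0; j < J; ++j) ll(i, j) = row_new[j];
        if (record_counts) ++acc_p[i];
      }
    }
    // beta_j updates
    for (int j = 0; j < J; ++j) {
      double prop = beta[j] + R::norm_rand() * s_beta[j];
      double d = 0.0;
      std::vector<double> col_new(L);
      for (int i = 0; i < L; ++i) {
        col_new[i] = loglik_cell(A(i, j), N(i, j), pi[i], alpha[i] + prop);
        d += col_new[i] - ll(i, j);
      }
      double dp = prop + 1.0, db = beta[j] + 1.0;       // N(-1,1) prior
      d += -0.5 * (dp * dp - db * db);
      if (record_counts) ++try_b[j];
      if (R_finite(d) && (d >= 0.0 || R::unif_rand() < std::exp(d))) {
        beta[j] = prop;
        for (int i = 0; i < L; ++i) ll(i, j) = col_new[i];
        if (record_counts) ++acc_b[j];
      }
    }
  };

  auto retune = [](std::vector<double>& s, std::vector<long>& tr,
                   std::vector<long>& ac) {
    for (size_t k = 0; k < s.size(); ++k) {
      if (tr[k] == 0) continue;
      double r = double(ac[k]) / double(tr[k]);
      if (r > 0.45) s[k] *= 1.5;
      else if (r < 0.25) s[k] /= 1.5;
      tr[k] = ac[k] = 0;
    }
  };

  for (int p = 0; p < pilot_runs; ++p) {
    for (int it = 0; it < pilot_length; ++it) sweep(true);
    retune(s_alpha, try_a, acc_a);
    retune(s_pi, try_p, acc_p);
    retune(s_beta, try_b, acc_b);
  }

  for (int it = 0; it < burn_in; ++it) sweep(false);

  // sampling phase: record every `thin` sweeps, track acceptance overall
  long need = (long)samples * thin;
  for (long it = 0; it < need; ++it) {
    sweep(true);
    if ((it + 1) % thin == 0) {
      for (int i = 0; i < L; ++i) {
        double m = 0.0;
        for (int j = 0; j < J; ++j)
          m += 1.0 / (1.0 + std::exp(-(alpha[i] + beta[j])));
        score[i] += m / J;
        alpha_mean[i] += alpha[i];
      }
      for (int j = 0; j < J; ++j) beta_mean[j] += beta[j];
      ++recorded;
    }
  }
  for (int i = 0; i < L; ++i) { score[i] /= recorded; alpha_mean[i] /= recorded; }

  double aa = 0, ta = 0, ap = 0, tp = 0, ab = 0, tb = 0;
  for (int i = 0; i < L; ++i) { aa += acc_a[i]; ta += try_a[i];
                                ap += acc_p[i]; tp += try_p[i]; }
  for (int j = 0; j < J; ++j) { ab += acc_b[j]; tb += try_b[j]; }
  NumericVector bm(J);
  for (int j = 0; j < J; ++j) bm[j] = beta_mean[j] / recorded;

  return List::create(
    _["score"] = score, _["alpha"] = alpha_mean, _["beta"] = bm,
    _["samples"] = recorded,
    _["acceptance"] = NumericVector::create(
      _["alpha"] = ta > 0 ? aa / ta : NA_REAL,
      _["pi"] = tp > 0 ? ap / tp : NA_REAL,
      _["beta"] = tb > 0 ? ab / tb : NA_REAL));
}
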