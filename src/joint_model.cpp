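// Joint hierarchical choice / response-time model: log posterior, analytic
// gradient, and a Hamiltonian Monte Carlo sampler.
//
// Model, per observed trial n with participant j = pid[n]:
//   eta    = X[n, ] . beta_j                  (logit of likelihood-of-take)
//   theta  = logistic(eta)
//   d      = 0.25 - (0.5 - theta)^2           (conflict statistic, in [0, .25])
//   mu     = alpha0_j + alpha1_j * d / d_denom
//   y[n]   ~ Bernoulli(theta)
//   z[n]   ~ Gamma(shape = k_j, rate = k_j / mu)   (mean mu)
//
// d_denom = 1 keeps the raw conflict scale; d_denom = 0.25 rescales d to
// [0, 1] so alpha1 reads as seconds of slowing at maximal conflict.
//
// Hierarchical parameterization is non-centered: beta_j = betaG + sd_b * u,
// u ~ N(0,1), ditto alpha0_j, alpha1_j. Group SDs and shapes live on the log
// scale. mu <= 0 yields log posterior -Inf (the sampler rejects).

#include <Rcpp.h>
using namespace Rcpp;

struct ModelData {
  NumericMatrix X;      // N x p choice design (col 0 = intercept)
  IntegerVector y;      // 0/1
  NumericVector z;      // RT seconds, > 0
  IntegerVector pid;    // 0-based participant index
  int np;               // number of participants
  double d_denom;       // 1 (raw) or 0.25 (unit)
  bool hierarchical;
  // prior hyperparameters
  double t_df, t_scale;           // Student-t on choice group means
  double a0_mean, a0_sd;          // normal on alpha0 group mean
  double a1_mean, a1_sd;          // normal on alpha1 group mean
  double hn_beta, hn_a0, hn_a1;   // half-normal scales for group SDs
  double k_shape, k_rate;         // gamma prior on participant shape k
};

// parameter packing (hierarchical), p = ncol(X):
//   [0, p)            group means betaG
//   [p]               alpha0G, [p+1] alpha1G
//   [p+2, 2p+2)       log group SDs of beta
//   [2p+2]            log sd alpha0, [2p+3] log sd alpha1
//   then per participant j: p raw beta offsets u_b, u_a0, u_a1, log k_j
// non-hierarchical: beta (p), alpha0, alpha1, log k  (one shared set)

static inline int dim_of(const ModelData& D) {
  int p = D.X.ncol();
  return D.hierarchical ? (2 * p + 4 + D.np * (p + 3)) : (p + 3);
}

// Student-t(df, 0, s) log density (unnormalized) and d/dx
static inline double t_lp(double x, double df, double s) {
  return -0.5 * (df + 1.0) * std::log1p(x * x / (df * s * s));
}
static inline double t_grad(double x, double df, double s) {
  return -(df + 1.0) * x / (df * s * s + x * x);
}

// log posterior and gradient; returns -Inf (grad untouched) when invalid
static double log_post_grad(const ModelData& D, const double* q, double* g,
                            bool want_grad) {
  const int p = D.X.ncol();
  const int N = D.X.nrow();
  const int dim = dim_of(D);
  if (want_grad) std::fill(g, g + dim, 0.0);

  double lp = 0.0;

  // unpack participant-level parameters
  std::vector<double> bj(D.np * p), a0j(D.np), a1j(D.np), kj(D.np);
  const double* gb = q;
  double ga0 = 0, ga1 = 0;
  std::vector<double> sb(p), u_off;
  double sa0 = 0, sa1 = 0;
  int poff = 0;

  if (D.hierarchical) {
    ga0 = q[p]; ga1 = q[p + 1];
    for (int c = 0; c < p; ++c) sb[c] = std::exp(q[p + 2 + c]);
    sa0 = std::exp(q[2 * p + 2]); sa1 = std::exp(q[2 * p + 3]);
    poff = 2 * p + 4;
    for (int j = 0; j < D.np; ++j) {
      const double* blk = q + poff + j * (p + 3);
      for (int c = 0; c < p; ++c) bj[j * p + c] = gb[c] + sb[c] * blk[c];
      a0j[j] = ga0 + sa0 * blk[p];
      a1j[j] = ga1 + sa1 * blk[p + 1];
      kj[j]  = std::exp(blk[p + 2]);
    }
  } else {
    ga0 = q[p]; ga1 = q[p + 1];
    double k1 = std::exp(q[p + 2]);
    for (int j = 0; j < D.np; ++j) {
      for (int c = 0; c < p; ++c) bj[j * p + c] = gb[c];
      a0j[j] = ga0; a1j[j] = ga1; kj[j] = k1;
    }
  }

  // likelihood
  std::vector<double> g_b(D.np * p, 0.0), g_a0(D.np, 0.0), g_a1(D.np, 0.0),
      g_lk(D.np, 0.0);
  for (int n = 0; n < N; ++n) {
    int j = D.pid[n];
    double eta = 0.0;
    for (int c = 0; c < p; ++c) eta += D.X(n, c) * bj[j * p + c];
    double theta = 1.0 / (1.0 + std::exp(-eta));
    // clamp to keep logs finite; gradient uses exact theta
    double th = std::min(std::max(theta, 1e-12), 1.0 - 1e-12);
    double d = 0.25 - (0.5 - theta) * (0.5 - theta);
    double du = d / D.d_denom;
    double k = kj[j];
    double mu = a0j[j] + a1j[j] * du;
    if (mu <= 0.0 || !std::isfinite(mu)) return R_NegInf;
    double zn = D.z[n];

    lp += D.y[n] ? std::log(th) : std::log(1.0 - th);
    lp += k * std::log(k / mu) - std::lgamma(k) + (k - 1.0) * std::log(zn) -
          k * zn / mu;

    if (want_grad) {
      double dll_dmu = k * (zn - mu) / (mu * mu);
      double g_eta = (D.y[n] - theta) +
                     dll_dmu * a1j[j] * (1.0 - 2.0 * theta) * theta *
                         (1.0 - theta) / D.d_denom;
      for (int c = 0; c < p; ++c) g_b[j * p + c] += g_eta * D.X(n, c);
      g_a0[j] += dll_dmu;
      g_a1[j] += dll_dmu * du;
      g_lk[j] += k * (std::log(k / mu) + 1.0 - R::digamma(k) + std::log(zn) -
                      zn / mu);
    }
  }

  // priors and chain rule to packed parameters
  if (D.hierarchical) {
    for (int c = 0; c < p; ++c) lp += t_lp(gb[c], D.t_df, D.t_scale);
    lp += -0.5 * (ga0 - D.a0_mean) * (ga0 - D.a0_mean) / (D.a0_sd * D.a0_sd);
    lp += -0.5 * (ga1 - D.a1_mean) * (ga1 - D.a1_mean) / (D.a1_sd * D.a1_sd);
    for (int c = 0; c < p; ++c)
      lp += -0.5 * sb[c] * sb[c] / (D.hn_beta * D.hn_beta) + q[p + 2 + c];
    lp += -0.5 * sa0 * sa0 / (D.hn_a0 * D.hn_a0) + q[2 * p + 2];
    lp += -0.5 * sa1 * sa1 / (D.hn_a1 * D.hn_a1) + q[2 * p + 3];
    for (int j = 0; j < D.np; ++j) {
      const double* blk = q + poff + j * (p + 3);
      for (int c = 0; c <= p + 1; ++c) lp += -0.5 * blk[c] * blk[c];
      // gamma prior on k with log-scale Jacobian
      lp += D.k_shape * blk[p + 2] - D.k_rate * kj[j];
    }
    if (!std::isfinite(lp)) return R_NegInf;
    if (want_grad) {
      for (int j = 0; j < D.np; ++j) {
        double* gblk = g + poff + j * (p + 3);
        const double* blk = q + poff + j * (p + 3);
        for (int c = 0; c < p; ++c) {
          g[c] += g_b[j * p + c];                       // group mean
          g[p + 2 + c] += g_b[j * p + c] * blk[c] * sb[c];  // log sd
          gblk[c] += g_b[j * p + c] * sb[c] - blk[c];   // raw offset + prior
        }
        g[p] += g_a0[j];
        g[p + 1] += g_a1[j];
        g[2 * p + 2] += g_a0[j] * blk[p] * sa0;
        g[2 * p + 3] += g_a1[j] * blk[p + 1] * sa1;
        gblk[p] += g_a0[j] * sa0 - blk[p];
        gblk[p + 1] += g_a1[j] * sa1 - blk[p + 1];
        gblk[p + 2] += g_lk[j] + D.k_shape - D.k_rate * kj[j];
      }
      for (int c = 0; c < p; ++c) g[c] += t_grad(gb[c], D.t_df, D.t_scale);
      g[p] += -(ga0 - D.a0_mean) / (D.a0_sd * D.a0_sd);
      g[p + 1] += -(ga1 - D.a1_mean) / (D.a1_sd * D.a1_sd);
      for (int c = 0; c < p; ++c)
        g[p + 2 + c] += -sb[c] * sb[c] / (D.hn_beta * D.hn_beta) + 1.0;
      g[2 * p + 2] += -sa0 * sa0 / (D.hn_a0 * D.hn_a0) + 1.0;
      g[2 * p + 3] += -sa1 * sa1 / (D.hn_a1 * D.hn_a1) + 1.0;
    }
  } else {
    for (int c = 0; c < p; ++c) lp += t_lp(gb[c], D.t_df, D.t_scale);
    lp += -0.5 * (ga0 - D.a0_mean) * (ga0 - D.a0_mean) / (D.a0_sd * D.a0_sd);
    lp += -0.5 * (ga1 - D.a1_mean) * (ga1 - D.a1_mean) / (D.a1_sd * D.a1_sd);
    double k1 = std::exp(q[p + 2]);
    lp += D.k_shape * q[p + 2] - D.k_rate * k1;
    if (!std::isfinite(lp)) return R_NegInf;
    if (want_grad) {
      for (int j = 0; j < D.np; ++j) {
        for (int c = 0; c < p; ++c) g[c] += g_b[j * p + c];
        g[p] += g_a0[j]; g[p + 1] += g_a1[j]; g[p + 2] += g_lk[j];
      }
      for (int c = 0; c < p; ++c) g[c] += t_grad(gb[c], D.t_df, D.t_scale);
      g[p] += -(ga0 - D.a0_mean) / (D.a0_sd * D.a0_sd);
      g[p + 1] += -(ga1 - D.a1_mean) / (D.a1_sd * D.a1_sd);
      g[p + 2] += D.k_shape - D.k_rate * k1;
    }
  }
  return lp;
}

static ModelData make_data(NumericMatrix X, IntegerVector y, NumericVector z,
                           IntegerVector pid, int np, double d_denom,
                           bool hierarchical, NumericVector prior) {
  ModelData D{X, y, z, pid, np, d_denom, hierarchical,
              prior["t_df"],    prior["t_scale"], prior["a0_mean"],
              prior["a0_sd"],   prior["a1_mean"], prior["a1_sd"],
              prior["hn_beta"], prior["hn_a0"],   prior["hn_a1"],
              prior["k_shape"], prior["k_rate"]};
  return D;
}

// [[Rcpp::export(name = ".cpp_log_post")]]
List cpp_log_post(NumericVector q, NumericMatrix X, IntegerVector y,
                  NumericVector z, IntegerVector pid, int np, double d_denom,
                  bool hierarchical, NumericVector prior) {
  ModelData D = make_data(X, y, z, pid, np, d_denom, hierarchical, prior);
  int dim = dim_of(D);
  if (q.size() != dim) stop("parameter vector has wrong length");
  NumericVector g(dim);
  double lp = log_post_grad(D, q.begin(), g.begin(), true);
  return List::create(_["lp"] = lp, _["grad"] = g);
}

// One HMC chain. Dual-averaging step-size adaptation toward `target_accept`
// during warmup; diagonal mass matrix estimated from the middle warmup
// window; trajectory length jittered uniformly on {1, ..., l_max}.
// Uses R's RNG: seed with set.seed() before calling for reproducibility.
// [[Rcpp::export(name = ".cpp_hmc_chain")]]
List cpp_hmc_chain(NumericVector q_init, int n_warmup, int n_samples, int thin,
                   int l_max, double target_accept, NumericMatrix X,
                   IntegerVector y, NumericVector z, IntegerVector pid, int np,
                   double d_denom, bool hierarchical, NumericVector prior) {
  RNGScope scope;
  ModelData D = make_data(X, y, z, pid, np, d_denom, hierarchical, prior);
  const int dim = dim_of(D);
  if (q_init.size() != dim) stop("init vector has wrong length");

  std::vector<double> q(q_init.begin(), q_init.end());
  std::vector<double> grad(dim), qp(dim), gp(dim), mom(dim);
  std::vector<double> inv_mass(dim, 1.0);

  double lp = log_post_grad(D, q.data(), grad.data(), true);
  if (!std::isfinite(lp)) stop("initial parameter values have zero posterior density");

  // dual averaging state
  double eps = 0.1, log_eps_bar = std::log(eps), h_bar = 0.0;
  double mu_da = std::log(10.0 * eps);
  const double gamma_da = 0.05, t0_da = 10.0, kappa_da = 0.75;
  int da_count = 0;

  // Welford accumulators for mass matrix (middle warmup window)
  std::vector<double> wm(dim, 0.0), ws(dim, 0.0);
  int wn = 0;
  const int mass_lo = n_warmup / 4, mass_hi = (3 * n_warmup) / 4;

  int kept = 0, n_keep = n_samples / thin;
  NumericMatrix draws(n_keep, dim);
  int n_div = 0;
  double acc_sum = 0.0; int acc_n = 0;

  const int total = n_warmup + n_samples;
  for (int it = 0; it < total; ++it) {
    bool warm = it < n_warmup;
    // refresh momentum: mom ~ N(0, M), M = 1/inv_mass
    for (int i = 0; i < dim; ++i) mom[i] = norm_rand() / std::sqrt(inv_mass[i]);
    double ke0 = 0.0;
    for (int i = 0; i < dim; ++i) ke0 += 0.5 * mom[i] * mom[i] * inv_mass[i];

    int L = 1 + (int)std::floor(unif_rand() * l_max);
    double e = eps * (0.9 + 0.2 * unif_rand());

    std::copy(q.begin(), q.end(), qp.begin());
    std::copy(grad.begin(), grad.end(), gp.begin());
    std::vector<double> pm(mom);
    double lpp = lp;
    bool diverged = false;
    for (int s = 0; s < L; ++s) {
      for (int i = 0; i < dim; ++i) pm[i] += 0.5 * e * gp[i];
      for (int i = 0; i < dim; ++i) qp[i] += e * pm[i] * inv_mass[i];
      lpp = log_post_grad(D, qp.data(), gp.data(), true);
      if (!std::isfinite(lpp)) { diverged = true; break; }
      for (int i = 0; i < dim; ++i) pm[i] += 0.5 * e * gp[i];
    }
    double alpha;
    if (diverged) {
      alpha = 0.0;
      if (!warm) ++n_div;
    } else {
      double ke1 = 0.0;
      for (int i = 0; i < dim; ++i) ke1 += 0.5 * pm[i] * pm[i] * inv_mass[i];
      double log_ratio = (lpp - ke1) - (lp - ke0);
      alpha = std::min(1.0, std::exp(log_ratio));
      if (unif_rand() < alpha) {
        std::swap(q, qp);
        std::swap(grad, gp);
        lp = lpp;
      }
    }

    if (warm) {
      // dual averaging
      ++da_count;
      double frac = 1.0 / (da_count + t0_da);
      h_bar = (1.0 - frac) * h_bar + frac * (target_accept - alpha);
      double log_eps = mu_da - std::sqrt((double)da_count) / gamma_da * h_bar;
      double w = std::pow((double)da_count, -kappa_da);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
      eps = std::exp(log_eps);
      if (it >= mass_lo && it < mass_hi) {
        ++wn;
        for (int i = 0; i < dim; ++i) {
          double dlt = q[i] - wm[i];
          wm[i] += dlt / wn;
          ws[i] += dlt * (q[i] - wm[i]);
        }
      }
      if (it == mass_hi - 1 && wn > 10) {
        for (int i = 0; i < dim; ++i) {
          double v = ws[i] / (wn - 1);
          inv_mass[i] = std::max(v, 1e-8);
        }
        // restart step-size adaptation under the new metric
        da_count = 0; h_bar = 0.0;
        eps = std::exp(log_eps_bar);
        mu_da = std::log(10.0 * eps);
      }
      if (it == n_warmup - 1) eps = std::exp(log_eps_bar);
    } else {
      acc_sum += alpha; ++acc_n;
      int post = it - n_warmup;
      if ((post + 1) % thin == 0 && kept < n_keep) {
        for (int i = 0; i < dim; ++i) draws(kept, i) = q[i];
        ++kept;
      }
    }
  }

  return List::create(_["draws"] = draws, _["step_size"] = eps,
                      _["accept_rate"] = acc_n ? acc_sum / acc_n : NA_REAL,
                      _["n_divergent"] = n_div);
}

// Pointwise joint log-likelihood matrix (draws x observations) for WAIC,
// from packed parameter draws.
// [[Rcpp::export(name = ".cpp_pointwise_loglik")]]
NumericMatrix cpp_pointwise_loglik(NumericMatrix draws, NumericMatrix X,
                                   IntegerVector y, NumericVector z,
                                   IntegerVector pid, int np, double d_denom,
                                   bool hierarchical) {
  const int p = X.ncol(), N = X.nrow(), S = draws.nrow();
  NumericMatrix out(S, N);
  std::vector<double> bj(np * p), a0j(np), a1j(np), kj(np);
  for (int s = 0; s < S; ++s) {
    // NumericMatrix is column-major; copy the row out
    std::vector<double> qs(draws.ncol());
    for (int c = 0; c < (int)qs.size(); ++c) qs[c] = draws(s, c);
    if (hierarchical) {
      double ga0 = qs[p], ga1 = qs[p + 1];
      std::vector<double> sb(p);
      for (int c = 0; c < p; ++c) sb[c] = std::exp(qs[p + 2 + c]);
      double sa0 = std::exp(qs[2 * p + 2]), sa1 = std::exp(qs[2 * p + 3]);
      int poff = 2 * p + 4;
      for (int j = 0; j < np; ++j) {
        const double* blk = qs.data() + poff + j * (p + 3);
        for (int c = 0; c < p; ++c) bj[j * p + c] = qs[c] + sb[c] * blk[c];
        a0j[j] = ga0 + sa0 * blk[p];
        a1j[j] = ga1 + sa1 * blk[p + 1];
        kj[j] = std::exp(blk[p + 2]);
      }
    } else {
      for (int j = 0; j < np; ++j) {
        for (int c = 0; c < p; ++c) bj[j * p + c] = qs[c];
        a0j[j] = qs[p]; a1j[j] = qs[p + 1]; kj[j] = std::exp(qs[p + 2]);
      }
    }
    for (int n = 0; n < N; ++n) {
      int j = pid[n];
      double eta = 0.0;
      for (int c = 0; c < p; ++c) eta += X(n, c) * bj[j * p + c];
      double theta = 1.0 / (1.0 + std::exp(-eta));
      double th = std::min(std::max(theta, 1e-12), 1.0 - 1e-12);
      double d = 0.25 - (0.5 - theta) * (0.5 - theta);
      double mu = a0j[j] + a1j[j] * d / d_denom;
      double k = kj[j];
      double ll = y[n] ? std::log(th) : std::log(1.0 - th);
      if (mu > 0) {
        ll += k * std::log(k / mu) - std::lgamma(k) +
              (k - 1.0) * std::log(z[n]) - k * z[n] / mu;
      } else {
        ll = R_NegInf;
      }
      out(s, n) = ll;
    }
  }
  return out;
}
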