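// MCMC for the participant-level trust-game decision model.
//
// Joint target: p(theta, E | trials) with theta the nine decision
// parameters and E one latent evaluation per trial. Sampling runs on an
// unconstrained scale (log transform for sigma_e, beta, sigma_m, with
// Jacobian terms), sweeping univariate slice updates over theta and
// per-trial slice updates over E. An adaptive componentwise
// random-walk Metropolis sampler is available as an independent
// cross-check. Uses R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
using namespace Rcpp;

// unconstrained parameter order
enum { U_WO, U_WA, U_WT, U_LSE, U_LBETA, U_GAMMA, U_S, U_C, U_LSM, NPAR };

struct Hyper {
  double w_a_mean, w_a_scale, w_t_mean, w_t_scale, w_o_mean, w_o_scale;
  double beta_shape, beta_scale, gamma_mean, gamma_scale;
  double sigma_e_scale, s_mean, s_scale, c_mean, c_scale, sigma_m_scale;
};

static const double HALF_LOG_2PI = 0.9189385332046727;

static inline double ldnorm(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -HALF_LOG_2PI - std::log(sd) - 0.5 * z * z;
}

// log sigmoid and log(1 - sigmoid), overflow-safe
static inline double log_mu(double z) {
  return z > 0 ? -std::log1p(std::exp(-z)) : z - std::log1p(std::exp(z));
}
static inline double log_1m_mu(double z) { return log_mu(-z); }

struct Model {
  int n;
  const double *a, *t, *m;
  const int *v;
  Hyper h;
  double sigma_floor;  // positivity floor on sigma_e, sigma_m

  // constrained values from unconstrained vector
  inline double sigma_e(const double* u) const {
    return std::exp(u[U_LSE]) + sigma_floor;
  }
  inline double beta(const double* u) const { return std::exp(u[U_LBETA]); }
  inline double sigma_m(const double* u) const {
    return std::exp(u[U_LSM]) + sigma_floor;
  }

  double logprior_jac(const double* u) const {
    double se = sigma_e(u), be = beta(u), sm = sigma_m(u);
    double lp = 0.0;
    lp += ldnorm(u[U_WA], h.w_a_mean, h.w_a_scale);
    lp += ldnorm(u[U_WT], h.w_t_mean, h.w_t_scale);
    lp += ldnorm(u[U_WO], h.w_o_mean, h.w_o_scale);
    lp += R::dgamma(be, h.beta_shape, h.beta_scale, 1);
    lp += ldnorm(u[U_GAMMA], h.gamma_mean, h.gamma_scale);
    // half-normal log densities
    lp += M_LN2 - HALF_LOG_2PI - std::log(h.sigma_e_scale)
        - 0.5 * (se / h.sigma_e_scale) * (se / h.sigma_e_scale);
    lp += ldnorm(u[U_S], h.s_mean, h.s_scale);
    lp += ldnorm(u[U_C], h.c_mean, h.c_scale);
    lp += M_LN2 - HALF_LOG_2PI - std::log(h.sigma_m_scale)
        - 0.5 * (sm / h.sigma_m_scale) * (sm / h.sigma_m_scale);
    // Jacobians of the log transforms
    lp += u[U_LSE] + u[U_LBETA] + u[U_LSM];
    return lp;
  }

  // likelihood contribution of trial j at evaluation E
  inline double ll_trial(const double* u, int j, double E) const {
    double mu_E = u[U_WO] + u[U_WA] * a[j] + u[U_WT] * t[j];
    double se = sigma_e(u);
    double z = beta(u) * (E - u[U_GAMMA]);
    double lp = ldnorm(E, mu_E, se);
    if (v[j] == 1) {
      lp += log_mu(z);
      lp += ldnorm(m[j], u[U_S] * E + u[U_C], sigma_m(u));
    } else {
      lp += log_1m_mu(z);
    }
    return lp;
  }

  double loglik(const double* u, const double* E) const {
    double lp = 0.0;
    for (int j = 0; j < n; ++j) lp += ll_trial(u, j, E[j]);
    return lp;
  }

  double lp_joint(const double* u, const double* E) const {
    return loglik(u, E) + logprior_jac(u);
  }

  // non-centered latent parameterization: E = mu_E + sigma_e * eta,
  // eta ~ N(0, 1). Decouples the evaluation noise scale from the
  // latents and keeps the sampling-space density bounded (the centered
  // joint density diverges as sigma_e -> 0 with E -> mu_E).
  inline double eval_of(const double* u, int j, double eta) const {
    return u[U_WO] + u[U_WA] * a[j] + u[U_WT] * t[j] + sigma_e(u) * eta;
  }

  inline double ll_trial_nc(const double* u, int j, double eta) const {
    double E = eval_of(u, j, eta);
    double z = beta(u) * (E - u[U_GAMMA]);
    double lp = -HALF_LOG_2PI - 0.5 * eta * eta;
    if (v[j] == 1) {
      lp += log_mu(z);
      lp += ldnorm(m[j], u[U_S] * E + u[U_C], sigma_m(u));
    } else {
      lp += log_1m_mu(z);
    }
    return lp;
  }

  double lp_joint_nc(const double* u, const double* eta) const {
    double lp = logprior_jac(u);
    for (int j = 0; j < n; ++j) lp += ll_trial_nc(u, j, eta[j]);
    return lp;
  }
};

// univariate slice sampler (Neal 2003, stepping out + shrinkage)
template <class F>
static double slice_update(double x0, double f0, F f, double w, int maxsteps,
                           double* f_out) {
  double logy = f0 - R::exp_rand();
  double L = x0 - w * unif_rand();
  double Rr = L + w;
  int jl = (int)std::floor(maxsteps * unif_rand());
  int jr = maxsteps - 1 - jl;
  while (jl-- > 0 && f(L) > logy) L -= w;
  while (jr-- > 0 && f(Rr) > logy) Rr += w;
  for (int it = 0; it < 1000; ++it) {
    double x1 = L + (Rr - L) * unif_rand();
    double f1 = f(x1);
    if (f1 >= logy) { *f_out = f1; return x1; }
    if (x1 < x0) L = x1; else Rr = x1;
  }
  *f_out = f0;
  return x0;  // shrinkage failed to move; keep current point
}

// [[Rcpp::export]]
List sample_participant_cpp(NumericVector a, NumericVector t,
                            IntegerVector v, NumericVector m,
                            List hyper, NumericVector init_u,
                            NumericVector init_E,
                            LogicalVector free_par,
                            int burnin, int keep, int thin,
                            std::string method,
                            NumericVector widths,
                            double sigma_floor) {
  Model mod;
  mod.n = a.size();
  mod.a = a.begin(); mod.t = t.begin(); mod.m = m.begin(); mod.v = v.begin();
  mod.sigma_floor = sigma_floor;
  Hyper& h = mod.h;
  h.w_a_mean = hyper["w_a_mean"];   h.w_a_scale = hyper["w_a_scale"];
  h.w_t_mean = hyper["w_t_mean"];   h.w_t_scale = hyper["w_t_scale"];
  h.w_o_mean = hyper["w_o_mean"];   h.w_o_scale = hyper["w_o_scale"];
  h.beta_shape = hyper["beta_shape"]; h.beta_scale = hyper["beta_scale"];
  h.gamma_mean = hyper["gamma_mean"]; h.gamma_scale = hyper["gamma_scale"];
  h.sigma_e_scale = hyper["sigma_e_scale"];
  h.s_mean = hyper["s_mean"]; h.s_scale = hyper["s_scale"];
  h.c_mean = hyper["c_mean"]; h.c_scale = hyper["c_scale"];
  h.sigma_m_scale = hyper["sigma_m_scale"];

  const int n = mod.n;
  const int total = burnin + keep * thin;
  std::vector<double> u(init_u.begin(), init_u.end());
  // convert initial evaluations to the non-centered scale
  std::vector<double> eta(n);
  {
    double se0 = mod.sigma_e(u.data());
    for (int j = 0; j < n; ++j) {
      double mu0 = u[U_WO] + u[U_WA] * a[j] + u[U_WT] * t[j];
      eta[j] = (init_E[j] - mu0) / se0;
    }
  }

  NumericMatrix theta_draws(keep, NPAR);
  NumericMatrix E_draws(keep, std::max(n, 1));
  NumericVector lp_trace(total);
  NumericVector lp_kept(keep);

  RNGScope rng;

  double cur_lp = mod.lp_joint_nc(u.data(), eta.data());
  if (!std::isfinite(cur_lp)) stop("non-finite log posterior at initialization");

  // adaptive RWM state
  std::vector<double> ls(NPAR, 0.0);       // log proposal sd per parameter
  for (int k = 0; k < NPAR; ++k) ls[k] = std::log(std::max(widths[k] / 4.0, 1e-3));
  double lsE = std::log(0.5);
  std::vector<int> acc(NPAR, 0), tries(NPAR, 0);
  int accE = 0, triesE = 0;
  const bool use_slice = (method == "slice");

  int kept_i = 0;
  for (int it = 0; it < total; ++it) {
    // ---- theta updates ----
    for (int k = 0; k < NPAR; ++k) {
      if (!free_par[k]) continue;
      if (use_slice) {
        double fx;
        auto f = [&](double x) {
          double old = u[k]; u[k] = x;
          double lp = mod.lp_joint_nc(u.data(), eta.data());
          u[k] = old;
          return lp;
        };
        double xn = slice_update(u[k], cur_lp, f, widths[k], 20, &fx);
        u[k] = xn; cur_lp = fx;
      } else {
        double old = u[k];
        u[k] = old + std::exp(ls[k]) * norm_rand();
        double prop_lp = mod.lp_joint_nc(u.data(), eta.data());
        tries[k]++;
        if (std::isfinite(prop_lp) &&
            std::log(unif_rand()) < prop_lp - cur_lp) {
          cur_lp = prop_lp; acc[k]++;
        } else {
          u[k] = old;
        }
      }
    }
    // ---- latent evaluation updates (local conditionals, eta scale) ----
    const double wEta = 1.0;  // eta is standard-normal a priori
    for (int j = 0; j < n; ++j) {
      double f0 = mod.ll_trial_nc(u.data(), j, eta[j]);
      if (use_slice) {
        double fx;
        auto f = [&](double x) { return mod.ll_trial_nc(u.data(), j, x); };
        double xn = slice_update(eta[j], f0, f, wEta, 20, &fx);
        cur_lp += fx - f0;
        eta[j] = xn;
      } else {
        double prop = eta[j] + std::exp(lsE) * norm_rand();
        double f1 = mod.ll_trial_nc(u.data(), j, prop);
        triesE++;
        if (std::isfinite(f1) && std::log(unif_rand()) < f1 - f0) {
          cur_lp += f1 - f0;
          eta[j] = prop;
          accE++;
        }
      }
    }
    // ---- ridge moves along the exact likelihood invariances ----
    // scale: (w, sigma_e) * lambda, (s, beta) / lambda, gamma * lambda
    // leaves every likelihood term identical (E scales with w and
    // sigma_e; eta is scale-free); only the prior and the Jacobian
    // (3 * log lambda on the unconstrained space) change. Without
    // these moves the componentwise sweeps crawl along the ridge.
    {
      auto apply_scale = [&](double l, double* w) {
        double el = std::exp(l);
        w[U_WO] = u[U_WO] * el; w[U_WA] = u[U_WA] * el;
        w[U_WT] = u[U_WT] * el; w[U_GAMMA] = u[U_GAMMA] * el;
        w[U_S] = u[U_S] / el;
        w[U_LSE] = u[U_LSE] + l; w[U_LBETA] = u[U_LBETA] - l;
        w[U_C] = u[U_C]; w[U_LSM] = u[U_LSM];
      };
      double prior0 = mod.logprior_jac(u.data());
      bool scale_free = free_par[U_WO] && free_par[U_WA] && free_par[U_WT] &&
        free_par[U_GAMMA] && free_par[U_S] && free_par[U_LSE] &&
        free_par[U_LBETA];
      if (scale_free) {
        double fx;
        auto f = [&](double l) {
          double w[NPAR]; apply_scale(l, w);
          return mod.logprior_jac(w) + 3.0 * l;
        };
        double l1 = slice_update(0.0, prior0, f, 0.3, 20, &fx);
        if (l1 != 0.0) {
          double w[NPAR]; apply_scale(l1, w);
          std::copy(w, w + NPAR, u.begin());
          cur_lp += mod.logprior_jac(u.data()) - prior0;
          prior0 = mod.logprior_jac(u.data());
        }
      }
      // location: w_o + d, gamma + d, c - s*d (shear, unit Jacobian)
      bool loc_free = free_par[U_WO] && free_par[U_GAMMA] && free_par[U_C];
      if (loc_free) {
        double fx;
        auto g = [&](double d) {
          double w[NPAR];
          std::copy(u.begin(), u.end(), w);
          w[U_WO] += d; w[U_GAMMA] += d; w[U_C] -= u[U_S] * d;
          return mod.logprior_jac(w);
        };
        double d1 = slice_update(0.0, prior0, g, 0.5, 20, &fx);
        if (d1 != 0.0) {
          u[U_WO] += d1; u[U_GAMMA] += d1; u[U_C] -= u[U_S] * d1;
          cur_lp += mod.logprior_jac(u.data()) - prior0;
        }
      }
    }

    // diminishing adaptation of RWM scales during burn-in
    if (!use_slice && it < burnin && ((it + 1) % 50 == 0)) {
      double step = std::min(0.25, 5.0 / std::sqrt((double)(it + 1)));
      for (int k = 0; k < NPAR; ++k) {
        if (tries[k] == 0) continue;
        double rate = (double)acc[k] / tries[k];
        ls[k] += (rate > 0.44 ? step : -step);
        acc[k] = tries[k] = 0;
      }
      if (triesE > 0) {
        double rateE = (double)accE / triesE;
        lsE += (rateE > 0.44 ? step : -step);
        accE = triesE = 0;
      }
    }

    lp_trace[it] = cur_lp;
    if (it >= burnin && ((it - burnin) % thin == 0)) {
      theta_draws(kept_i, U_WO) = u[U_WO];
      theta_draws(kept_i, U_WA) = u[U_WA];
      theta_draws(kept_i, U_WT) = u[U_WT];
      theta_draws(kept_i, U_LSE) = mod.sigma_e(u.data());
      theta_draws(kept_i, U_LBETA) = mod.beta(u.data());
      theta_draws(kept_i, U_GAMMA) = u[U_GAMMA];
      theta_draws(kept_i, U_S) = u[U_S];
      theta_draws(kept_i, U_C) = u[U_C];
      theta_draws(kept_i, U_LSM) = mod.sigma_m(u.data());
      for (int j = 0; j < n; ++j)
        E_draws(kept_i, j) = mod.eval_of(u.data(), j, eta[j]);
      lp_kept[kept_i] = cur_lp;
      kept_i++;
    }
  }

  return List::create(_["theta"] = theta_draws, _["E"] = E_draws,
                      _["lp_trace"] = lp_trace, _["lp_kept"] = lp_kept);
}

// 31-point Gauss-Hermite rule (integral of exp(-x^2) f(x) dx)
static const int GH_N = 31;
static const double GH_X[GH_N] = {
  -6.9956801237185298e+00, -6.2750787049428576e+00, -5.6739614446185938e+00,
  -5.1335955771123816e+00, -4.6315595063128550e+00, -4.1562717558181452e+00,
  -3.7007434032314697e+00, -3.2603207323135388e+00, -2.8316804533902014e+00,
  -2.4123177054804197e+00, -2.0002585489356361e+00, -1.5938858604721338e+00,
  -1.1918269983500425e+00, -7.9287697691530479e-01, -3.9594273647142053e-01,
  0.0,
  3.9594273647142497e-01, 7.9287697691531278e-01, 1.1918269983500487e+00,
  1.5938858604721409e+00, 2.0002585489356379e+00, 2.4123177054804206e+00,
  2.8316804533902049e+00, 3.2603207323135419e+00, 3.7007434032314692e+00,
  4.1562717558181452e+00, 4.6315595063128594e+00, 5.1335955771123807e+00,
  5.6739614446185875e+00, 6.2750787049428594e+00, 6.9956801237185404e+00 };
static const double GH_W[GH_N] = {
  4.6189683944645579e-22, 5.1106090079272692e-18, 5.8995564987532911e-15,
  1.8603735214520128e-12, 2.3524920032086237e-10, 1.4611988344909875e-08,
  5.0437125589394895e-07, 1.0498602757675540e-05, 1.3952090395046753e-04,
  1.2336833073068796e-03, 7.4827999140350057e-03, 3.1847230731299983e-02,
  9.6717948160870940e-02, 2.1213278866876734e-01, 3.3877265789410915e-01,
  3.9577855609860896e-01, 3.3877265789410371e-01, 2.1213278866876167e-01,
  9.6717948160872078e-02, 3.1847230731301114e-02, 7.4827999140353258e-03,
  1.2336833073069049e-03, 1.3952090395047135e-04, 1.0498602757675603e-05,
  5.0437125589398547e-07, 1.4611988344910574e-08, 2.3524920032086697e-10,
  1.8603735214521651e-12, 5.8995564987539656e-15, 5.1106090079271783e-18,
  4.6189683944641432e-22 };

// Marginal log likelihood p(v, m | theta): the latent evaluation of
// each trial is integrated out by Gauss-Hermite quadrature against its
// Gaussian prior N(mu_E, sigma_e^2). One value per theta draw
// (constrained scale, columns in canonical order).
// [[Rcpp::export]]
NumericVector marginal_loglik_cpp(NumericMatrix theta,
                                  NumericVector a, NumericVector t,
                                  IntegerVector v, NumericVector m) {
  const int ndraw = theta.nrow(), n = a.size();
  const double SQRT_PI = std::sqrt(M_PI), SQRT2 = std::sqrt(2.0);
  NumericVector out(ndraw);
  for (int i = 0; i < ndraw; ++i) {
    double w_o = theta(i, 0), w_a = theta(i, 1), w_t = theta(i, 2);
    double se = theta(i, 3), be = theta(i, 4), ga = theta(i, 5);
    double s = theta(i, 6), c = theta(i, 7), sm = theta(i, 8);
    double tot = 0.0;
    for (int j = 0; j < n; ++j) {
      double mu_E = w_o + w_a * a[j] + w_t * t[j];
      double acc = 0.0, mx = -INFINITY;
      double terms[GH_N];
      for (int k = 0; k < GH_N; ++k) {
        double E = mu_E + SQRT2 * se * GH_X[k];
        double z = be * (E - ga);
        double lt = (v[j] == 1)
          ? log_mu(z) + ldnorm(m[j], s * E + c, sm)
          : log_1m_mu(z);
        terms[k] = lt;
        if (lt > mx) mx = lt;
      }
      if (!std::isfinite(mx)) { tot = -INFINITY; break; }
      for (int k = 0; k < GH_N; ++k)
        acc += GH_W[k] * std::exp(terms[k] - mx);
      tot += mx + std::log(acc / SQRT_PI);
    }
    out[i] = tot;
  }
  return out;
}

// joint log posterior on the constrained scale, used to cross-check the
// R implementation (no Jacobian terms: theta given directly)
// [[Rcpp::export]]
double lp_joint_cpp(NumericVector theta, NumericVector E,
                    NumericVector a, NumericVector t,
                    IntegerVector v, NumericVector m, List hyper) {
  Model mod;
  mod.n = a.size();
  mod.a = a.begin(); mod.t = t.begin(); mod.m = m.begin(); mod.v = v.begin();
  mod.sigma_floor = 0.0;
  Hyper& h = mod.h;
  h.w_a_mean = hyper["w_a_mean"];   h.w_a_scale = hyper["w_a_scale"];
  h.w_t_mean = hyper["w_t_mean"];   h.w_t_scale = hyper["w_t_scale"];
  h.w_o_mean = hyper["w_o_mean"];   h.w_o_scale = hyper["w_o_scale"];
  h.beta_shape = hyper["beta_shape"]; h.beta_scale = hyper["beta_scale"];
  h.gamma_mean = hyper["gamma_mean"]; h.gamma_scale = hyper["gamma_scale"];
  h.sigma_e_scale = hyper["sigma_e_scale"];
  h.s_mean = hyper["s_mean"]; h.s_scale = hyper["s_scale"];
  h.c_mean = hyper["c_mean"]; h.c_scale = hyper["c_scale"];
  h.sigma_m_scale = hyper["sigma_m_scale"];

  double u[NPAR];
  u[U_WO] = theta[0]; u[U_WA] = theta[1]; u[U_WT] = theta[2];
  u[U_LSE] = std::log(theta[3]); u[U_LBETA] = std::log(theta[4]);
  u[U_GAMMA] = theta[5]; u[U_S] = theta[6]; u[U_C] = theta[7];
  u[U_LSM] = std::log(theta[8]);
  // subtract the Jacobian terms logprior_jac adds
  return mod.loglik(u, E.begin()) + mod.logprior_jac(u)
       - (u[U_LSE] + u[U_LBETA] + u[U_LSM]);
}
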