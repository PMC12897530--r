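# shared fixtures and independent density oracles

PAR9 <- c("w_o", "w_a", "w_t", "sigma_e", "beta", "gamma", "s", "c", "sigma_m")

# a small, fully valid long-format behavior table built by hand
make_behavior_fixture <- function() {
  expand_part <- function(id, group, a, t, m) {
    data.frame(participant_id = id, group = group,
               partner_id = sprintf("P%d", seq_along(a)),
               attractiveness = a, trustworthiness = t, amount = m)
  }
  rbind(
    expand_part("S1", "HC", c(2, 5, 7), c(3, 4, 8), c(0, 300, 1300)),
    expand_part("S2", "MDD", c(1, 1, 9), c(2, 2, 9), c(100, 0, 700)))
}

# trials simulated from known parameters, in validated table form
make_synth_trials <- function(params, n = 50, seed = 1,
                              id = "SX", group = "HC") {
  set.seed(seed)
  a <- sample(0:9, n, replace = TRUE)
  t <- sample(0:9, n, replace = TRUE)
  sim <- sample_trials(params, a, t)
  validate_behavior(
    data.frame(participant_id = id, group = group,
               partner_id = sprintf("P%03d", seq_len(n)),
               attractiveness = a, trustworthiness = t,
               amount = sim$amount))
}

# deterministic low-noise participant: bimodal evaluations far from the
# invest threshold, so decisions and amounts are almost noiseless
make_deterministic_participant <- function(seed = 5) {
  set.seed(seed)
  truth <- participant_params(w_o = 0, w_a = 0.5, w_t = 0.5,
                              sigma_e = 0.03, beta = 200, gamma = 4.5,
                              s = 100, c = 300, sigma_m = 3)
  a <- c(rep(0:3, 5), rep(6:9, 5))
  t <- c(rep(c(1, 3, 0, 2), 5), rep(c(8, 6, 9, 7), 5))
  sim <- sample_trials(truth, a, t)
  trials <- validate_behavior(
    data.frame(participant_id = "DET", group = "HC",
               partner_id = sprintf("P%02d", seq_along(a)),
               attractiveness = a, trustworthiness = t,
               amount = sim$amount))
  list(truth = truth, trials = trials)
}

# ---- independent density oracles (coded from the definitions, not ----
# ---- via the package's internals) ----
oracle_lnorm <- function(x, mean, sd) dnorm(x, mean, sd, log = TRUE)
oracle_lhalfnorm <- function(x, scale) {
  ifelse(x >= 0, log(2) + dnorm(x, 0, scale, log = TRUE), -Inf)
}
oracle_logprior <- function(p, h = hyper_priors()) {
  oracle_lnorm(p["w_a"], h$w_a_mean, h$w_a_scale) +
    oracle_lnorm(p["w_t"], h$w_t_mean, h$w_t_scale) +
    oracle_lnorm(p["w_o"], h$w_o_mean, h$w_o_scale) +
    dgamma(p["beta"], shape = h$beta_shape, scale = h$beta_scale, log = TRUE) +
    oracle_lnorm(p["gamma"], h$gamma_mean, h$gamma_scale) +
    oracle_lhalfnorm(p["sigma_e"], h$sigma_e_scale) +
    oracle_lnorm(p["s"], h$s_mean, h$s_scale) +
    oracle_lnorm(p["c"], h$c_mean, h$c_scale) +
    oracle_lhalfnorm(p["sigma_m"], h$sigma_m_scale)
}
oracle_loglik_one <- function(p, E, a, t, v, m) {
  mu_E <- p["w_o"] + p["w_a"] * a + p["w_t"] * t
  mu <- 1 / (1 + exp(-p["beta"] * (E - p["gamma"])))
  ll <- oracle_lnorm(E, mu_E, p["sigma_e"]) +
    ifelse(v == 1, log(mu), log(1 - mu))
  if (v == 1) ll <- ll + oracle_lnorm(m, p["s"] * E + p["c"], p["sigma_m"])
  unname(ll)
}

# exhaustive two-sided rank-sum p-value by enumerating every split
oracle_ranksum_exact_p <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v)
  idx <- utils::combn(n, length(x))
  r <- rank(all_v)
  w_obs <- sum(r[seq_along(x)])
  ws <- apply(idx, 2, function(i) sum(r[i]))
  mu <- length(x) * (n + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# textbook BH step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}
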