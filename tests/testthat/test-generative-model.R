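test_that("evaluation and amount means evaluate the linear forms", {
  p0 <- participant_params(w_o = 0, w_a = 0, w_t = 0)
  expect_equal(evaluation_mean(p0, 3, 8), 0)
  p1 <- participant_params(w_o = 0, w_a = 1, w_t = 0)
  expect_equal(evaluation_mean(p1, 7, 2), 7)
  p2 <- participant_params(w_o = 1, w_a = 0.5, w_t = 0.3)
  expect_equal(evaluation_mean(p2, 4, 6), 4.8)
  expect_equal(evaluation_mean(p2, c(4, 0), c(6, 0)), c(4.8, 1))
  ps <- participant_params(s = 1, c = 0)
  expect_equal(amount_mean(ps, 5), 5)
  expect_equal(amount_mean(participant_params(s = 0, c = 500), -3), 500)
  expect_equal(amount_mean(participant_params(s = 100, c = 100), 4.8), 580)
})

test_that("invest probability is a stable logistic in the evaluation", {
  expect_equal(invest_probability(1.7, beta = 3, gamma = 1.7), 0.5)
  expect_equal(invest_probability(2, beta = 2, gamma = 1), 1 / (1 + exp(-2)))
  # saturation without overflow
  expect_equal(invest_probability(1000, beta = 1, gamma = 0), 1)
  expect_equal(invest_probability(-1000, beta = 1, gamma = 0), 0)
  expect_error(invest_probability(0, beta = -1, gamma = 0), "beta")
  # strictly increasing and point-symmetric about gamma
  E <- seq(-5, 5, by = 0.25)
  p <- invest_probability(E, beta = 1.3, gamma = 0.4)
  expect_true(all(diff(p) > 0))
  expect_equal(p, 1 - invest_probability(2 * 0.4 - E, beta = 1.3, gamma = 0.4))
})

test_that("trial log likelihood matches an independent density oracle", {
  p <- participant_params(w_o = 0.3, w_a = 0.45, w_t = 0.25, sigma_e = 0.7,
                          beta = 3.2, gamma = 1.1, s = 95, c = 240,
                          sigma_m = 110)
  tr <- data.frame(participant_id = "X", partner_id = c("A", "B", "C"),
                   attractiveness = c(2, 8, 5), trustworthiness = c(3, 7, 0),
                   amount = c(0, 700, 400))
  tr <- validate_behavior(tr)
  E <- c(0.8, 4.1, 2.0)
  got <- loglik_trials(p, E, tr, per_trial = TRUE)
  want <- vapply(1:3, function(j)
    oracle_loglik_one(p, E[j], tr$attractiveness[j], tr$trustworthiness[j],
                      tr$invest[j], tr$amount[j]), 0)
  expect_equal(got, want, tolerance = 1e-10)
  # non-invested trial has no amount term: independent of s, c, sigma_m
  p2 <- p; p2["s"] <- 7; p2["c"] <- 1; p2["sigma_m"] <- 3
  expect_equal(loglik_trials(p, E[1], tr[1, ]),
               loglik_trials(p2, E[1], tr[1, ]))
  # invest = 0 with nonzero amount is impossible
  bad <- tr; bad$invest[2] <- 0L
  expect_error(loglik_trials(p, E, bad), "impossible")
})

test_that("per-trial likelihood density normalizes over (E, m)", {
  p <- participant_params(w_o = 0.5, w_a = 0.3, w_t = 0.2, sigma_e = 0.6,
                          beta = 2.5, gamma = 1.4, s = 90, c = 300,
                          sigma_m = 80)
  a <- 4; t <- 6
  Egrid <- seq(-6, 10, length.out = 801)
  dE <- Egrid[2] - Egrid[1]
  mgrid <- seq(-600, 1800, length.out = 1201)
  dm <- mgrid[2] - mgrid[1]
  mk_trial <- function(amount) validate_behavior(data.frame(
    participant_id = "X", partner_id = "A", attractiveness = a,
    trustworthiness = t, amount = amount))
  # v = 0: mass at m = 0, density over E only
  f0 <- vapply(Egrid, function(E) exp(loglik_trials(p, E, mk_trial(0))), 0)
  mass0 <- sum(f0) * dE
  # v = 1: density over (E, m); quadrature over the continuous grid
  tr1 <- mk_trial(100)
  mass1 <- 0
  for (E in Egrid) {
    mu_E <- evaluation_mean(p, a, t)
    base <- dnorm(E, mu_E, p[["sigma_e"]]) *
      invest_probability(E, p[["beta"]], p[["gamma"]])
    mass1 <- mass1 + base * sum(dnorm(mgrid, amount_mean(p, E),
                                      p[["sigma_m"]])) * dm * dE
  }
  expect_equal(unname(mass0 + mass1), 1, tolerance = 1e-3)
})

test_that("log prior matches the oracle and respects support", {
  h <- hyper_priors()
  p <- participant_params(w_o = 0, w_a = 0, w_t = 0, sigma_e = 0.5,
                          beta = 4, gamma = 1, s = 100, c = 100,
                          sigma_m = 100)
  expect_equal(logprior(p, h), unname(oracle_logprior(p, h)),
               tolerance = 1e-10)
  set.seed(4)
  for (i in 1:10) {
    q <- p
    q[PAR9] <- abs(rnorm(9, as.numeric(p), c(1, 1, 1, .3, 2, 1, 50, 50, 50)))
    expect_equal(logprior(q, h), unname(oracle_logprior(q, h)),
                 tolerance = 1e-10)
  }
  bad <- unclass(p); bad["beta"] <- -1
  expect_equal(logprior(bad, h), -Inf)
  bad2 <- unclass(p); bad2["sigma_m"] <- 0
  expect_equal(logprior(bad2, h), -Inf)
  # doubling the w_a prior scale reduces the penalty for w_a != 0
  h2 <- hyper_priors(w_a_scale = 2)
  q <- p; q["w_a"] <- 1.5
  expect_gt(logprior(q, h2), logprior(q, h))
})

test_that("log posterior is additive over trials and equals the prior at n = 0", {
  p <- participant_params(w_o = 0.2, w_a = 0.5, w_t = 0.1, sigma_e = 0.4,
                          beta = 5, gamma = 0.8, s = 120, c = 180,
                          sigma_m = 95)
  h <- hyper_priors()
  empty <- validate_behavior(make_behavior_fixture())[0, ]
  expect_equal(logposterior(p, numeric(0), empty, h), logprior(p, h))
  tr <- validate_behavior(make_behavior_fixture())
  tr <- tr[tr$participant_id == "S1", ]
  E <- c(1.1, 2.6, 4.0)
  lp <- logposterior(p, E, tr, h)
  brute <- sum(vapply(1:3, function(j)
    oracle_loglik_one(p, E[j], tr$attractiveness[j], tr$trustworthiness[j],
                      tr$invest[j], tr$amount[j]), 0)) +
    unname(oracle_logprior(p, h))
  expect_equal(lp, brute, tolerance = 1e-10)
  # duplicating a trial adds exactly its term
  tr2 <- validate_behavior(rbind(tr, transform(tr[2, ], partner_id = "P9")))
  lp2 <- logposterior(p, setNames(c(E, E[2]), c(tr$partner_id, "P9")), tr2, h)
  expect_equal(lp2 - lp, loglik_trials(p, E[2], tr[2, ]), tolerance = 1e-10)
  # mismatched partner coverage
  expect_error(logposterior(p, setNames(E, c("P1", "P2", "PX")), tr, h),
               "cover")
})

test_that("forward simulation honors the response grids and the seed", {
  p <- participant_params(w_o = 0, w_a = 0.5, w_t = 0.5, sigma_e = 0.5,
                          beta = 5, gamma = 1, s = 100, c = 300,
                          sigma_m = 100)
  set.seed(7); s1 <- sample_trials(p, 0:9, 9:0)
  set.seed(7); s2 <- sample_trials(p, 0:9, 9:0)
  expect_identical(s1, s2)
  set.seed(8)
  big <- sample_trials(p, rep(0:9, 100), rep(9:0, 100))
  expect_true(all(big$amount %in% c(0, seq(100, 1300, by = 100))))
  expect_true(all(big$amount[big$invest == 0] == 0))
  expect_true(all(big$amount[big$invest == 1] >= 100))
  # saturated sigmoid: investment forced
  forced <- participant_params(beta = 50, gamma = -100)
  set.seed(9)
  expect_true(all(sample_trials(forced, rep(5, 1e4), rep(5, 1e4))$invest == 1))
  # degenerate amount policy
  fixed <- participant_params(s = 0, c = 500, sigma_m = 1e-6,
                              beta = 50, gamma = -100)
  set.seed(10)
  expect_true(all(sample_trials(fixed, rep(5, 100), rep(5, 100))$amount == 500))
})

test_that("Monte-Carlo invest frequency converges to the sigmoid", {
  p <- participant_params(beta = 2, gamma = 1)
  set.seed(11)
  for (E in c(0.0, 1.0, 2.5)) {
    mu <- invest_probability(E, p["beta"], p["gamma"])
    v <- rbinom(1e5, 1, mu)  # the sampler's decision rule at fixed E
    se <- sqrt(mu * (1 - mu) / 1e5)
    expect_lt(abs(mean(v) - mu), 3 * se + 1e-12)
  }
  # through the full forward model at tiny evaluation noise
  pf <- participant_params(w_o = 2, w_a = 0, w_t = 0, sigma_e = 1e-8,
                           beta = 2, gamma = 1)
  set.seed(12)
  sim <- sample_trials(pf, rep(0, 1e5), rep(0, 1e5))
  mu <- invest_probability(2, 2, 1)
  expect_lt(abs(mean(sim$invest) - mu), 3 * sqrt(mu * (1 - mu) / 1e5))
})
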