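# Reduced draw counts keep these unit tests quick; the full-scale
# posterior checks live in test-acceptance.R.

test_that("fits are reproducible under a seed and respect positivity", {
  det <- make_deterministic_participant()
  mc <- mcmc_settings(burnin = 200, draws = 200)
  f1 <- fit_participant(det$trials, mcmc = mc, seed = 42)
  f2 <- fit_participant(det$trials, mcmc = mc, seed = 42)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$lp_trace, f2$lp_trace)
  f3 <- fit_participant(det$trials, mcmc = mc, seed = 43)
  expect_false(identical(f1$theta, f3$theta))
  expect_true(all(f1$theta[, c("sigma_e", "beta", "sigma_m")] > 0))
  expect_equal(nrow(f1$theta), 200)
  expect_length(f1$lp_trace, 400)
})

test_that("prior-only fits reproduce analytic prior moments", {
  empty <- validate_behavior(make_behavior_fixture())[0, ]
  fit <- fit_participant(empty, mcmc = mcmc_settings(burnin = 500,
                                                     draws = 2000),
                         seed = 3)
  th <- fit$theta
  checks <- list(
    beta = 5,                      # gamma mean: shape * scale
    sigma_e = 0.5 * sqrt(2 / pi),  # half-normal mean
    sigma_m = 100 * sqrt(2 / pi),
    w_a = 0, w_t = 0, w_o = 0, gamma = 1, s = 100, c = 100)
  for (nm in names(checks)) {
    mcse <- mcse_batch(th[, nm])
    expect_lt(abs(mean(th[, nm]) - checks[[nm]]), 3 * mcse + 1e-9)
  }
})

test_that("MAP takes the earliest highest-scoring kept draw", {
  det <- make_deterministic_participant()
  fit <- fit_participant(det$trials,
                         mcmc = mcmc_settings(burnin = 300, draws = 300),
                         seed = 9)
  m <- map_estimate(fit)
  expect_s3_class(m, "participant_params")
  i <- attr(m, "map_index")
  expect_equal(as.numeric(m), as.numeric(fit$theta[i, PAR9]))
  # joint-density scoring picks the argmax of the recorded trace
  mj <- map_estimate(fit, joint = TRUE)
  expect_equal(attr(mj, "map_index"), which.max(fit$lp_kept))
  # ties resolve to the earliest draw
  tied <- fit
  tied$lp_kept <- rep(1, length(fit$lp_kept))
  tj <- map_estimate(tied, joint = TRUE)
  expect_equal(attr(tj, "map_index"), 1L)
  expect_error(map_estimate(list(lp_kept = numeric(0))), "empty")
})

test_that("MAP recovers a sharply peaked synthetic posterior", {
  truth <- participant_params(w_o = 0.3, w_a = 0.5, w_t = 0.4,
                              sigma_e = 0.4, beta = 5, gamma = 1,
                              s = 100, c = 300, sigma_m = 100)
  trials <- make_synth_trials(truth, n = 500, seed = 14)
  fit <- fit_participant(trials, mcmc = mcmc_settings(burnin = 800,
                                                      draws = 800),
                         seed = 15)
  m <- map_estimate(fit)
  psd <- apply(fit$theta, 2, sd)
  for (nm in PAR9)
    expect_lt(abs(m[[nm]] - truth[[nm]]), 3 * psd[nm] + 1e-9)
})

test_that("convergence check flags trends and passes stationary traces", {
  set.seed(21)
  white <- rnorm(2000)
  expect_true(check_convergence(white)$passes)
  trend <- seq(0, 10, length.out = 2000) + rnorm(2000, sd = 0.1)
  expect_false(check_convergence(trend)$passes)
  det <- make_deterministic_participant()
  fit <- fit_participant(det$trials,
                         mcmc = mcmc_settings(burnin = 500, draws = 500),
                         seed = 2)
  cc <- check_convergence(fit)
  expect_true(cc$passes)
  expect_true(is.finite(cc$half_shift_sd))
  expect_error(check_convergence(c(1, 2)), "too short")
})

test_that("point predictions follow the sigmoid and amount policy", {
  partners <- data.frame(partner_id = c("A", "B"),
                         attractiveness = c(8, 1), trustworthiness = c(9, 0))
  # saturated regime: probability ~ 1, expected amount ~ s*E + c
  p <- participant_params(w_o = 0, w_a = 0.5, w_t = 0.5, beta = 60,
                          gamma = 0.2, s = 100, c = 100)
  pr <- predict_trials(p, partners)
  expect_equal(pr$invest_prob, c(1, 1), tolerance = 1e-6)
  expect_equal(pr$conditional_amount,
               amount_mean(p, evaluation_mean(p, partners$attractiveness,
                                              partners$trustworthiness)))
  # flat weights at threshold: probability exactly 1/2
  p0 <- participant_params(w_o = 0, w_a = 0, w_t = 0, beta = 1, gamma = 0)
  expect_equal(predict_trials(p0, partners)$invest_prob, c(0.5, 0.5))
})

test_that("mean-mode predictions track the forward-simulation oracle", {
  p <- participant_params(w_o = 0.2, w_a = 0.4, w_t = 0.3, sigma_e = 0.5,
                          beta = 3, gamma = 2, s = 100, c = 300,
                          sigma_m = 80)
  partners <- data.frame(attractiveness = c(2, 5, 8),
                         trustworthiness = c(1, 6, 9))
  set.seed(31)
  mc <- predict_trials(p, partners, mode = "mc", n_mc = 2e4)
  # oracle: raw forward simulation through sample_trials
  for (j in 1:3) {
    set.seed(100 + j)
    sims <- sample_trials(p, rep(partners$attractiveness[j], 1e5),
                          rep(partners$trustworthiness[j], 1e5))
    se_p <- sd(sims$invest) / sqrt(1e5)
    expect_lt(abs(mc$invest_prob[j] - mean(sims$invest)), 4 * se_p)
    se_m <- sd(sims$amount) / sqrt(1e5)
    expect_lt(abs(mc$expected_amount[j] - mean(sims$amount)),
              4 * se_m + 4 * sd(sims$amount) / sqrt(2e4))
  }
})

test_that("cross-validation scores a deterministic participant perfectly", {
  det <- make_deterministic_participant()
  cv <- cross_validate(det$trials, n_train = 30, n_test = 10, seed = 8,
                       mcmc = mcmc_settings(burnin = 800, draws = 800,
                                            thin = 2))
  expect_setequal(c(cv$train_partner_ids, cv$test_partner_ids),
                  as.character(unique(det$trials$partner_id)))
  expect_length(intersect(cv$train_partner_ids, cv$test_partner_ids), 0)
  expect_equal(cv$invest_accuracy, 1.0)
  expect_gte(cv$amount_r2, 0.99)
})

test_that("r2 is flagged undefined on constant test observations", {
  det <- make_deterministic_participant()
  tr <- det$trials
  tr$amount <- 500  # constant responder
  tr$invest <- 1L
  cv <- cross_validate(tr, n_train = 30, n_test = 10, seed = 3,
                       mcmc = mcmc_settings(burnin = 300, draws = 300))
  expect_false(cv$r2_defined)
  expect_true(is.na(cv$amount_r2))
})

test_that("perfect and null predictions bracket the r2 scale", {
  obs <- c(0, 300, 500, 700, 1200)
  expect_equal(cor(obs, obs)^2, 1)
  set.seed(41)
  x <- rnorm(100); y <- rnorm(100)
  expect_lt(cor(x, y)^2, 0.1)
})

test_that("slice and Metropolis samplers agree on posterior means", {
  truth <- participant_params(w_o = 0.2, w_a = 0.5, w_t = 0.3,
                              sigma_e = 0.5, beta = 5, gamma = 1,
                              s = 100, c = 300, sigma_m = 100)
  trials <- make_synth_trials(truth, n = 80, seed = 51)
  fs <- fit_participant(trials, mcmc = mcmc_settings(burnin = 1500,
                                                     draws = 3000),
                        seed = 52)
  fr <- fit_participant(trials,
                        mcmc = mcmc_settings(burnin = 4000, draws = 12000,
                                             method = "rwm"),
                        seed = 53)
  for (nm in c("w_a", "w_t", "gamma", "s", "c", "sigma_m")) {
    tol <- 3 * (mcse_batch(fs$theta[, nm]) + mcse_batch(fr$theta[, nm]))
    expect_lt(abs(mean(fs$theta[, nm]) - mean(fr$theta[, nm])), tol)
  }
})

test_that("posterior contracts as trials accumulate", {
  truth <- participant_params(w_o = 0.2, w_a = 0.5, w_t = 0.3,
                              sigma_e = 0.5, beta = 5, gamma = 1,
                              s = 100, c = 300, sigma_m = 100)
  mc <- mcmc_settings(burnin = 600, draws = 600)
  sd40 <- apply(fit_participant(make_synth_trials(truth, 40, seed = 61),
                                mcmc = mc, seed = 62)$theta, 2, sd)
  sd400 <- apply(fit_participant(make_synth_trials(truth, 400, seed = 63),
                                 mcmc = mc, seed = 64)$theta, 2, sd)
  expect_lt(median(sd400 / sd40), 1)
  for (nm in c("w_a", "w_t", "s", "sigma_m"))
    expect_lt(sd400[nm], sd40[nm])
})
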