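#' Default MCMC sampler settings
#'
#' @param burnin Discarded initial sweeps (2000 by default).
#' @param draws Kept draws after burn-in (4000 by default).
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param method `"slice"` (slice-sampling-within-Gibbs, default) or
#'   `"rwm"` (adaptive componentwise random-walk Metropolis, kept as an
#'   independent cross-check sampler).
#' @param sigma_floor Positivity floor added to `sigma_e`, `sigma_m` on
#'   the unconstrained scale, guarding against degenerate densities.
#' @return List of settings.
#' @export
mcmc_settings <- function(burnin = 2000, draws = 4000, thin = 1,
                          method = c("slice", "rwm"), sigma_floor = 1e-6) {
  method <- match.arg(method)
  stopifnot(burnin >= 0, draws > 0, thin >= 1)
  list(burnin = as.integer(burnin), draws = as.integer(draws),
       thin = as.integer(thin), method = method, sigma_floor = sigma_floor)
}

# unconstrained <-> constrained maps (log transform on the positives)
u_to_theta <- function(u) {
  c(w_o = u[1], w_a = u[2], w_t = u[3], sigma_e = exp(u[4]), beta = exp(u[5]),
    gamma = u[6], s = u[7], c = u[8], sigma_m = exp(u[9]))
}
theta_to_u <- function(p) {
  unname(c(p["w_o"], p["w_a"], p["w_t"], log(p["sigma_e"]), log(p["beta"]),
           p["gamma"], p["s"], p["c"], log(p["sigma_m"])))
}

default_init <- function(hyper, trials) {
  p <- c(w_o = hyper$w_o_mean, w_a = hyper$w_a_mean, w_t = hyper$w_t_mean,
         sigma_e = max(hyper$sigma_e_scale, 1e-3),
         beta = hyper$beta_shape * hyper$beta_scale,
         gamma = hyper$gamma_mean, s = hyper$s_mean, c = hyper$c_mean,
         sigma_m = max(hyper$sigma_m_scale, 1e-3))
  E <- if (nrow(trials)) {
    ifelse(trials$invest == 1,
           pmax(pmin((trials$amount - p["c"]) / ifelse(abs(p["s"]) < 1, 1, p["s"]),
                     50), -50),
           p["gamma"] - 1)
  } else numeric(0)
  list(p = p, E = as.numeric(E))
}

#' Fit the decision model to one participant's trials by MCMC
#'
#' Samples the joint posterior of the nine decision parameters and the
#' per-trial latent evaluations, on an unconstrained reparameterization
#' (log scale for `beta`, `sigma_e`, `sigma_m`, Jacobians included).
#' The log-posterior trace is recorded for every sweep, burn-in
#' included. Zero-trial input is allowed and samples the prior.
#'
#' @param trials Trial data frame for one participant (validated
#'   behavior rows); may have zero rows.
#' @param hyper [hyper_priors()].
#' @param mcmc [mcmc_settings()].
#' @param seed Integer seed; the fit is reproducible under it.
#' @param fixed Optional named numeric of parameters to clamp (e.g.
#'   `c(w_a = 0.5)`); clamped parameters are held at these values and
#'   not sampled.
#' @param participant_id Identifier stored in the result.
#' @return Object of class `posterior_draws`: list with `theta` (draws x
#'   9 matrix, constrained scale), `E` (draws x trials matrix,
#'   partner-labelled), `lp_trace` (all sweeps), `lp_kept`, and
#'   `meta`.
#' @export
fit_participant <- function(trials, hyper = hyper_priors(),
                            mcmc = mcmc_settings(), seed = 1L,
                            fixed = NULL, participant_id = NA_character_) {
  if (nrow(trials) > 0 && nrow(trials) < 2 && is.null(fixed))
    stop("need at least 2 trials to fit all parameters", call. = FALSE)
  init <- default_init(hyper, trials)
  p0 <- init$p
  free <- rep(TRUE, 9)
  names(free) <- PARAM_NAMES
  if (!is.null(fixed)) {
    stopifnot(all(names(fixed) %in% PARAM_NAMES))
    p0[names(fixed)] <- fixed
    free[names(fixed)] <- FALSE
  }
  widths <- c(1, 1, 1, 1, 0.5, 1, 50, 50, 1)  # unconstrained-scale step sizes

  set.seed(seed)
  res <- NULL
  for (attempt in 1:5) {
    u0 <- theta_to_u(p0)
    E0 <- init$E
    if (attempt > 1) {  # jittered re-initialization
      u0 <- u0 + rnorm(9, 0, 0.1)
      if (length(E0)) E0 <- E0 + rnorm(length(E0), 0, 0.1)
    }
    res <- tryCatch(
      sample_participant_cpp(
        as.numeric(trials$attractiveness), as.numeric(trials$trustworthiness),
        as.integer(trials$invest), as.numeric(trials$amount),
        unclass(hyper), u0, E0, free,
        mcmc$burnin, mcmc$draws, mcmc$thin, mcmc$method, widths,
        mcmc$sigma_floor),
      error = function(e) e)
    if (!inherits(res, "error")) break
  }
  if (inherits(res, "error"))
    stop("sampler failed after 5 re-initializations: ",
         conditionMessage(res), call. = FALSE)

  colnames(res$theta) <- PARAM_NAMES
  if (nrow(trials)) colnames(res$E) <- as.character(trials$partner_id)
  structure(
    list(participant_id = participant_id,
         trials = trials,
         theta = res$theta,
         E = if (nrow(trials)) res$E else res$E[, 0, drop = FALSE],
         lp_trace = res$lp_trace,
         lp_kept = res$lp_kept,
         meta = list(burnin = mcmc$burnin, draws = mcmc$draws,
                     thin = mcmc$thin, seed = seed, sampler = mcmc$method,
                     n_trials = nrow(trials))),
    class = "posterior_draws")
}

#' MAP estimate from posterior draws
#'
#' The kept draw with the highest log posterior density of the
#' parameters (earliest draw on ties). Each kept draw is scored by its
#' marginal posterior density: the per-trial latent evaluations are
#' integrated out by Gauss-Hermite quadrature, then the log prior is
#' added. Scoring draws by the joint (theta, E) density instead is
#' available via `joint = TRUE` but is discouraged: the joint density
#' is unbounded along noise-collapse directions, which systematically
#' distorts the argmax draw. Posterior means are attached as attribute
#' `"posterior_mean"` as a secondary estimator.
#'
#' @param draws `posterior_draws`.
#' @param hyper [hyper_priors()] used for the prior term (defaults to
#'   the reference prior).
#' @param joint Score draws by the sampled joint density instead of the
#'   marginal parameter density.
#' @return `participant_params` with attributes `posterior_mean`,
#'   `map_index` and `lp_map`.
#' @export
map_estimate <- function(draws, hyper = hyper_priors(), joint = FALSE) {
  if (!length(draws$lp_kept)) stop("empty draws", call. = FALSE)
  lp <- if (joint || draws$meta$n_trials == 0) {
    draws$lp_kept
  } else {
    tr <- draws$trials
    marginal_loglik_cpp(draws$theta[, PARAM_NAMES, drop = FALSE],
                        as.numeric(tr$attractiveness),
                        as.numeric(tr$trustworthiness),
                        as.integer(tr$invest), as.numeric(tr$amount)) +
      apply(draws$theta, 1, logprior, hyper = hyper)
  }
  i <- which.max(lp)  # which.max returns the first maximum
  p <- setNames(as.numeric(draws$theta[i, PARAM_NAMES]), PARAM_NAMES)
  class(p) <- c("participant_params", "numeric")
  attr(p, "posterior_mean") <- colMeans(draws$theta)
  attr(p, "map_index") <- i
  attr(p, "lp_map") <- lp[i]
  p
}

#' @export
print.participant_params <- function(x, digits = 3, ...) {
  print(round(setNames(as.numeric(x[PARAM_NAMES]), PARAM_NAMES), digits))
  invisible(x)
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> participant %s: %d kept draws (%s), %d trials\n",
              x$participant_id, nrow(x$theta), x$meta$sampler,
              x$meta$n_trials))
  invisible(x)
}

#' Marginal log likelihood of a parameter draw
#'
#' `log p(v, m | theta)` with the latent evaluations integrated out by
#' Gauss-Hermite quadrature (31 nodes per trial).
#'
#' @param params `participant_params` (or a draws x 9 matrix).
#' @param trials Trial data frame.
#' @return Numeric vector, one value per parameter row.
#' @export
marginal_loglik <- function(params, trials) {
  th <- if (is.matrix(params)) params[, PARAM_NAMES, drop = FALSE]
        else matrix(params[PARAM_NAMES], 1, 9,
                    dimnames = list(NULL, PARAM_NAMES))
  marginal_loglik_cpp(th, as.numeric(trials$attractiveness),
                      as.numeric(trials$trustworthiness),
                      as.integer(trials$invest), as.numeric(trials$amount))
}

#' Posterior-mean latent evaluations
#' @param draws `posterior_draws`.
#' @return Named numeric, one posterior-mean evaluation per partner.
#' @export
posterior_mean_evaluations <- function(draws) {
  colMeans(draws$E)
}

#' Convergence check on the log-posterior trace
#'
#' Splits the post-burn-in trace in half and reports the mean shift
#' between halves in post-burn-in SD units; the chain passes when the
#' shift is below `max_shift` SDs. Mirrors a visual trace-stabilization
#' check with a numeric rule.
#'
#' @param draws `posterior_draws` (or a bare numeric trace via
#'   `trace`).
#' @param max_shift Pass threshold in SD units.
#' @param burnin Burn-in length when a bare trace is supplied.
#' @return List: `mean`, `sd`, `half_shift_sd`, `passes`.
#' @export
check_convergence <- function(draws, max_shift = 0.5, burnin = NULL) {
  trace <- if (inherits(draws, "posterior_draws")) {
    draws$lp_trace[-seq_len(draws$meta$burnin)]
  } else {
    if (!is.null(burnin) && burnin > 0) draws[-seq_len(burnin)] else draws
  }
  if (length(trace) < 4) stop("trace too short", call. = FALSE)
  half <- length(trace) %/% 2
  m1 <- mean(trace[seq_len(half)])
  m2 <- mean(trace[(half + 1):length(trace)])
  s <- sd(trace)
  shift <- if (s > 0) abs(m2 - m1) / s else 0
  list(mean = mean(trace), sd = s, half_shift_sd = shift,
       passes = shift < max_shift)
}

#' Predict invest decisions and amounts for rated partners
#'
#' Point predictions evaluate the model at the mean evaluation `E =
#' w_o + w_a*a + w_t*t` (evaluation noise integrated at its mean):
#' invest probability `mu(E)`, unconditional expected amount
#' `mu(E)*(s*E + c)`, and the invest-conditional mean `s*E + c`. The
#' Monte-Carlo mode (`mode = "mc"`) instead integrates over the
#' evaluation noise and the forward model's amount quantization by
#' simulation.
#'
#' @param params `participant_params`.
#' @param partners Data frame with `attractiveness`, `trustworthiness`
#'   (and optionally `partner_id`).
#' @param mode `"mean"` (default) or `"mc"`.
#' @param n_mc Monte-Carlo draws per partner for `mode = "mc"`.
#' @param config [model_config()] (quantization grid for MC mode).
#' @return Data frame `partner_id, invest_prob, expected_amount,
#'   conditional_amount`.
#' @export
predict_trials <- function(params, partners, mode = c("mean", "mc"),
                           n_mc = 10000, config = model_config()) {
  mode <- match.arg(mode)
  validate_params(params)
  a <- partners$attractiveness
  t <- partners$trustworthiness
  ids <- if (!is.null(partners$partner_id)) partners$partner_id
         else seq_along(a)
  if (mode == "mean") {
    Ebar <- evaluation_mean(params, a, t)
    p <- invest_probability(Ebar, params["beta"], params["gamma"])
    cond <- amount_mean(params, Ebar)
    return(data.frame(partner_id = ids, invest_prob = p,
                      expected_amount = p * cond, conditional_amount = cond))
  }
  out <- lapply(seq_along(a), function(j) {
    E <- rnorm(n_mc, evaluation_mean(params, a[j], t[j]), params["sigma_e"])
    mu <- invest_probability(E, params["beta"], params["gamma"])
    m <- quantize_amount(rnorm(n_mc, amount_mean(params, E),
                               params["sigma_m"]), config)
    p <- mean(mu)
    ua <- mean(mu * m)
    data.frame(partner_id = ids[j], invest_prob = p, expected_amount = ua,
               conditional_amount = if (p > 0) ua / p else NA_real_)
  })
  do.call(rbind, out)
}

#' Cross-validated prediction for one participant
#'
#' Splits the participant's partners uniformly at random into train and
#' test sets, fits the model on the training trials, and scores the
#' MAP point predictions on the held-out partners: invest decisions
#' classified at probability 0.5 and scored by accuracy, amounts scored
#' by the squared Pearson correlation between predicted expected
#' amounts and observed amounts (`r2_method = "regression"` gives the
#' through-origin regression R^2 instead).
#'
#' @param trials One participant's validated trials.
#' @param hyper [hyper_priors()].
#' @param n_train,n_test Partner counts; must sum to the partner count.
#' @param seed Integer seed (partition and sampler).
#' @param mcmc [mcmc_settings()].
#' @param r2_method `"pearson"` (default) or `"regression"`.
#' @return List with `train_partner_ids`, `test_partner_ids`,
#'   `invest_accuracy`, `amount_r2`, `r2_defined`, `predictions` (the
#'   per-test-partner predicted/observed pairs), `map_params`.
#' @export
cross_validate <- function(trials, hyper = hyper_priors(),
                           n_train = NULL, n_test = NULL, seed = 1L,
                           mcmc = mcmc_settings(),
                           r2_method = c("pearson", "regression")) {
  r2_method <- match.arg(r2_method)
  partners <- as.character(unique(trials$partner_id))
  np <- length(partners)
  if (is.null(n_train)) n_train <- floor(3 * np / 4)
  if (is.null(n_test)) n_test <- np - n_train
  if (n_train + n_test != np)
    stop("n_train + n_test must equal the partner count (", np, ")",
         call. = FALSE)
  set.seed(seed)
  train_ids <- sort(sample(partners, n_train))
  test_ids <- setdiff(partners, train_ids)
  train <- trials[trials$partner_id %in% train_ids, ]
  test <- trials[trials$partner_id %in% test_ids, ]

  fit <- fit_participant(train, hyper, mcmc, seed = seed,
                         participant_id = as.character(trials$participant_id[1]))
  map <- map_estimate(fit)
  pred <- predict_trials(map, test)
  obs_v <- test$invest
  obs_m <- test$amount
  acc <- mean(as.integer(pred$invest_prob >= 0.5) == obs_v)
  r2_defined <- sd(obs_m) > 0 && sd(pred$expected_amount) > 0
  r2 <- if (!r2_defined) NA_real_
        else if (r2_method == "pearson") cor(pred$expected_amount, obs_m)^2
        else {  # regression through the origin
          b <- sum(pred$expected_amount * obs_m) / sum(pred$expected_amount^2)
          1 - sum((obs_m - b * pred$expected_amount)^2) /
              sum((obs_m - mean(obs_m))^2)
        }
  list(participant_id = as.character(trials$participant_id[1]),
       train_partner_ids = train_ids, test_partner_ids = test_ids,
       invest_accuracy = acc, amount_r2 = r2, r2_defined = r2_defined,
       predictions = cbind(pred, observed_invest = obs_v,
                           observed_amount = obs_m),
       map_params = map)
}

#' Batch-means Monte-Carlo standard error
#' @param x Draws of a scalar quantity.
#' @return MCSE accounting for autocorrelation via sqrt(n) batches.
#' @export
mcse_batch <- function(x) {
  n <- length(x)
  b <- max(2L, floor(sqrt(n)))
  nb <- n %/% b
  bm <- vapply(seq_len(nb), function(i) mean(x[((i - 1) * b + 1):(i * b)]), 0)
  sd(bm) / sqrt(nb)
}
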