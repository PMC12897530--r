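#' Mean latent evaluation of a partner
#'
#' The latent evaluation E combines a participant's two face ratings
#' through participant-specific weights: `E ~ N(w_o + w_a*a + w_t*t,
#' sigma_e^2)`. This returns the Gaussian mean.
#'
#' @param params `participant_params`.
#' @param attractiveness,trustworthiness Ratings (vectorized).
#' @return Numeric vector of evaluation means.
#' @export
evaluation_mean <- function(params, attractiveness, trustworthiness) {
  unname(params["w_o"] + params["w_a"] * attractiveness +
           params["w_t"] * trustworthiness)
}

#' Probability of deciding to invest
#'
#' Logistic in the latent evaluation: `mu(E) = 1 / (1 + exp(-beta * (E -
#' gamma)))`. `beta` controls decision randomness (steepness), `gamma`
#' the evaluation threshold at which investing becomes more likely than
#' not. Numerically stable for large `|beta * (E - gamma)|`.
#'
#' @param E Latent evaluation (vectorized).
#' @param beta Steepness, > 0.
#' @param gamma Threshold.
#' @return Probabilities in `[0, 1]`.
#' @export
invest_probability <- function(E, beta, gamma) {
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  stats::plogis(beta * (E - gamma))
}

#' Mean invested amount given the evaluation
#'
#' Linear amount policy `m = s*E + c` (JPY), the mean of the Gaussian
#' amount distribution used when the participant invests.
#'
#' @param params `participant_params`.
#' @param E Latent evaluation (vectorized).
#' @return Mean amounts in JPY.
#' @export
amount_mean <- function(params, E) {
  unname(params["s"] * E + params["c"])
}

# log N(x | mu, sd) without dnorm's argument checking (hot path)
ldnorm <- function(x, mu, sd) {
  -0.5 * log(2 * pi) - log(sd) - 0.5 * ((x - mu) / sd)^2
}

# log of half-normal density with scale sigma0, support x >= 0
ldhalfnorm <- function(x, sigma0) {
  ifelse(x >= 0,
         log(2) - 0.5 * log(2 * pi) - log(sigma0) - 0.5 * (x / sigma0)^2,
         -Inf)
}

# stable log(mu) and log(1-mu) for the logistic mu = plogis(z)
log_mu <- function(z) -log1p(exp(-pmin(z, 700)))   # log sigmoid
log_one_minus_mu <- function(z) -log1p(exp(pmin(z, 700)))

#' Log-likelihood of one or more trials given the latent evaluations
#'
#' Per trial: `log N(E | w.r, sigma_e^2) + log Bernoulli(v | mu(E)) + v *
#' log N(m | s*E + c, sigma_m^2)`. A non-invested trial has all its
#' amount mass at m = 0 (delta), so its amount term is exactly zero; a
#' non-invested trial with a nonzero amount is an impossible observation
#' and raises an error.
#'
#' @param params `participant_params`.
#' @param E Latent evaluation(s), one per trial.
#' @param trials Data frame with `attractiveness`, `trustworthiness`,
#'   `amount`, `invest`.
#' @param per_trial Return the vector of per-trial terms instead of the
#'   sum.
#' @return Log-density (scalar, or vector when `per_trial = TRUE`).
#' @export
loglik_trials <- function(params, E, trials, per_trial = FALSE) {
  stopifnot(length(E) == nrow(trials))
  v <- trials$invest
  if (any(v == 0 & trials$amount != 0))
    stop("impossible observation: invest = 0 with nonzero amount",
         call. = FALSE)
  mu_E <- evaluation_mean(params, trials$attractiveness, trials$trustworthiness)
  z <- params["beta"] * (E - params["gamma"])
  ll <- ldnorm(E, mu_E, params["sigma_e"]) +
    ifelse(v == 1, log_mu(z), log_one_minus_mu(z)) +
    v * ldnorm(trials$amount, params["s"] * E + params["c"], params["sigma_m"])
  ll <- unname(ll)
  if (per_trial) ll else sum(ll)
}

#' @rdname loglik_trials
#' @param trial Single-row trial data frame.
#' @export
loglik_trial <- function(params, E, trial) {
  loglik_trials(params, E, trial)
}

#' Log prior density of the nine decision parameters
#'
#' Normal priors on `w_a, w_t, w_o, gamma, s, c`; Gamma on `beta`;
#' half-normal on `sigma_e` and `sigma_m`. Returns `-Inf` outside the
#' support (`beta <= 0` or a nonpositive noise scale).
#'
#' @param params `participant_params` (plain named numeric accepted).
#' @param hyper [hyper_priors()].
#' @return Scalar log-density.
#' @export
logprior <- function(params, hyper = hyper_priors()) {
  p <- params
  if (p["beta"] <= 0 || p["sigma_e"] <= 0 || p["sigma_m"] <= 0) return(-Inf)
  unname(
    ldnorm(p["w_a"], hyper$w_a_mean, hyper$w_a_scale) +
    ldnorm(p["w_t"], hyper$w_t_mean, hyper$w_t_scale) +
    ldnorm(p["w_o"], hyper$w_o_mean, hyper$w_o_scale) +
    dgamma(p["beta"], shape = hyper$beta_shape, scale = hyper$beta_scale,
           log = TRUE) +
    ldnorm(p["gamma"], hyper$gamma_mean, hyper$gamma_scale) +
    ldhalfnorm(p["sigma_e"], hyper$sigma_e_scale) +
    ldnorm(p["s"], hyper$s_mean, hyper$s_scale) +
    ldnorm(p["c"], hyper$c_mean, hyper$c_scale) +
    ldhalfnorm(p["sigma_m"], hyper$sigma_m_scale))
}

#' Joint log posterior of parameters and latent evaluations
#'
#' Sum of the per-trial log-likelihood terms and the log prior, up to
#' the normalizing constant. The latent evaluations are kept explicit
#' (one per trial); the sigmoid-times-normal product has no closed-form
#' marginal, so no analytic marginalization is attempted.
#'
#' @param params `participant_params`.
#' @param E Named or positional vector of latent evaluations, one per
#'   trial (matched to `trials` rows; names, when present, must match
#'   `trials$partner_id`).
#' @param trials Trial data frame for one participant.
#' @param hyper [hyper_priors()].
#' @return Scalar log-density.
#' @export
logposterior <- function(params, E, trials, hyper = hyper_priors()) {
  if (!is.null(names(E))) {
    if (!setequal(names(E), as.character(trials$partner_id)))
      stop("latent evaluations do not cover the trial partner set",
           call. = FALSE)
    E <- E[as.character(trials$partner_id)]
  } else if (length(E) != nrow(trials)) {
    stop("need one latent evaluation per trial", call. = FALSE)
  }
  ll <- if (nrow(trials)) loglik_trials(params, E, trials) else 0
  ll + logprior(params, hyper)
}

#' Simulate trials forward from the generative model
#'
#' Draws `E ~ N(w.r, sigma_e^2)`, the invest decision `v ~
#' Bernoulli(mu(E))`, and, when invested, a raw Gaussian amount `N(s*E +
#' c, sigma_m^2)` quantized to the nearest 100 JPY and clipped to `[100,
#' 1300]`; non-invested trials have amount 0. Quantization and clipping
#' live only here, in the forward direction: the likelihood treats the
#' amount as continuous.
#'
#' @param params `participant_params`.
#' @param attractiveness,trustworthiness Rating vectors (recycled to a
#'   common length).
#' @param config [model_config()].
#' @return Data frame `attractiveness, trustworthiness, E, invest,
#'   amount`.
#' @export
sample_trials <- function(params, attractiveness, trustworthiness,
                          config = model_config()) {
  n <- max(length(attractiveness), length(trustworthiness))
  a <- rep_len(attractiveness, n)
  t <- rep_len(trustworthiness, n)
  E <- rnorm(n, evaluation_mean(params, a, t), params["sigma_e"])
  v <- rbinom(n, 1, invest_probability(E, params["beta"], params["gamma"]))
  raw <- rnorm(n, amount_mean(params, E), params["sigma_m"])
  m <- quantize_amount(raw, config)
  m[v == 0] <- 0
  data.frame(attractiveness = a, trustworthiness = t, E = E,
             invest = v, amount = m)
}

# nearest-step rounding then clip into the positive amount grid
quantize_amount <- function(raw, config = model_config()) {
  step <- config$amount_step
  m <- round(raw / step) * step
  pmin(pmax(m, step), config$amount_max)
}
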