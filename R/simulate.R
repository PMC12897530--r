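#' Synthetic cohort specification
#'
#' Describes a trust-game cohort: group sizes, shared photographed
#' partners with correlated latent attractiveness/trustworthiness
#' traits, per-participant decision parameters drawn from population
#' distributions, and an optional group offset on the basal evaluation
#' weight. Defaults emulate the reference study design: 38 + 38
#' participants, 40 partners, discrete 0--9 ratings, 100-JPY amount
#' steps, and no group difference in decision parameters.
#'
#' @param n_hc,n_mdd Participants per group.
#' @param n_partners Shared photographed partners.
#' @param trait_mean,trait_sd Latent partner trait location/spread on
#'   the rating scale (both traits).
#' @param trait_cor Correlation between latent attractiveness and
#'   trustworthiness across partners.
#' @param rating_noise_sd Rater noise SD added before discretization.
#' @param param_mean,param_sd Named numerics over the nine decision
#'   parameters: population mean and SD of each participant-specific
#'   parameter (positives are truncated below at `param_floor`).
#' @param mdd_w_o_offset Additive MDD-group shift on `w_o` (0 by
#'   default: no group difference).
#' @param param_floor Truncation floor for `sigma_e`, `beta`,
#'   `sigma_m`.
#' @param config [model_config()].
#' @return List with class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_hc = 38, n_mdd = 38, n_partners = 40,
                        trait_mean = 4.5, trait_sd = 1.8, trait_cor = 0.5,
                        rating_noise_sd = 1,
                        param_mean = c(w_o = 0, w_a = 0.4, w_t = 0.4,
                                       sigma_e = 0.5, beta = 5, gamma = 1,
                                       s = 100, c = 300, sigma_m = 100),
                        param_sd = c(w_o = 0.3, w_a = 0.15, w_t = 0.15,
                                     sigma_e = 0.1, beta = 1.5, gamma = 0.5,
                                     s = 20, c = 80, sigma_m = 20),
                        mdd_w_o_offset = 0, param_floor = 0.05,
                        config = model_config()) {
  stopifnot(n_hc >= 0, n_mdd >= 0, n_hc + n_mdd > 0, n_partners > 0,
            trait_sd >= 0, rating_noise_sd >= 0,
            abs(trait_cor) <= 1,
            all(PARAM_NAMES %in% names(param_mean)),
            all(PARAM_NAMES %in% names(param_sd)),
            all(param_sd >= 0))
  structure(list(n_hc = n_hc, n_mdd = n_mdd, n_partners = n_partners,
                 trait_mean = trait_mean, trait_sd = trait_sd,
                 trait_cor = trait_cor, rating_noise_sd = rating_noise_sd,
                 param_mean = param_mean, param_sd = param_sd,
                 mdd_w_o_offset = mdd_w_o_offset, param_floor = param_floor,
                 config = config),
            class = "cohort_spec")
}

# round half-up, then clip into the discrete rating range
discretize_rating <- function(x, rating_max = 9) {
  pmin(pmax(floor(x + 0.5), 0), rating_max)
}

draw_participant_params <- function(spec, group) {
  p <- rnorm(9, spec$param_mean[PARAM_NAMES], spec$param_sd[PARAM_NAMES])
  names(p) <- PARAM_NAMES
  pos <- c("sigma_e", "beta", "sigma_m")
  p[pos] <- pmax(p[pos], spec$param_floor)
  if (group == "MDD") p["w_o"] <- p["w_o"] + spec$mdd_w_o_offset
  p
}

#' Generate a synthetic trust-game cohort
#'
#' Partner latent traits are drawn once and shared by every participant
#' (the real stimuli are fixed photographs); each participant's ratings
#' add rater noise and are discretized to the 0--9 scale. Decisions and
#' amounts then follow the forward model ([sample_trials()]), so
#' amounts land on the 100-JPY grid with zeros exactly on non-invested
#' trials.
#'
#' @param spec [cohort_spec()].
#' @param seed Integer seed.
#' @return List: `behavior` (validated long table with `group`),
#'   `truth` (data frame of true per-participant parameters plus
#'   group), `evaluations` (participants x partners matrix of the true
#'   latent evaluations E_ij), `partner_traits`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  set.seed(seed)
  np <- spec$n_partners
  # correlated latent partner traits
  z1 <- rnorm(np); z2 <- rnorm(np)
  A <- spec$trait_mean + spec$trait_sd * z1
  Tt <- spec$trait_mean + spec$trait_sd *
    (spec$trait_cor * z1 + sqrt(1 - spec$trait_cor^2) * z2)
  partner_ids <- sprintf("P%02d", seq_len(np))

  groups <- c(rep("HC", spec$n_hc), rep("MDD", spec$n_mdd))
  pids <- sprintf("S%03d", seq_along(groups))
  rmax <- spec$config$rating_max

  rows <- vector("list", length(pids))
  truth <- vector("list", length(pids))
  evals <- matrix(NA_real_, length(pids), np,
                  dimnames = list(pids, partner_ids))
  for (i in seq_along(pids)) {
    par_i <- draw_participant_params(spec, groups[i])
    a <- discretize_rating(A + rnorm(np, 0, spec$rating_noise_sd), rmax)
    t <- discretize_rating(Tt + rnorm(np, 0, spec$rating_noise_sd), rmax)
    sim <- sample_trials(structure(par_i, class = c("participant_params",
                                                    "numeric")),
                         a, t, spec$config)
    rows[[i]] <- data.frame(participant_id = pids[i], group = groups[i],
                            partner_id = partner_ids,
                            attractiveness = sim$attractiveness,
                            trustworthiness = sim$trustworthiness,
                            amount = sim$amount)
    evals[i, ] <- sim$E
    truth[[i]] <- cbind(data.frame(participant_id = pids[i],
                                   group = groups[i]),
                        as.data.frame(as.list(par_i)))
  }
  behavior <- validate_behavior(do.call(rbind, rows), spec$config)
  list(behavior = behavior, truth = do.call(rbind, truth),
       evaluations = evals,
       partner_traits = data.frame(partner_id = partner_ids,
                                   attractiveness = A, trustworthiness = Tt))
}

#' Inject non-serious (constant) responders into a cohort
#'
#' Replaces a fraction of participants with constant responders: one
#' fixed rating pair and one fixed amount for every partner, so every
#' response channel has zero Shannon entropy. These are the
#' participants the entropy QC is meant to exclude.
#'
#' @param spec [cohort_spec()].
#' @param fraction Proportion of participants made non-serious (exact
#'   count `round(fraction * n)`).
#' @param seed Integer seed.
#' @return As [generate_cohort()], plus `nonserious_ids`.
#' @export
generate_nonserious <- function(spec = cohort_spec(), fraction = 0.25,
                                seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  cohort <- generate_cohort(spec, seed)
  pids <- unique(cohort$behavior$participant_id)
  n_ns <- round(fraction * length(pids))
  if (n_ns == 0) return(c(cohort, list(nonserious_ids = character(0))))
  ns_ids <- sort(sample(pids, n_ns))
  opts <- spec$config$amount_options
  for (id in ns_ids) {
    idx <- cohort$behavior$participant_id == id
    cohort$behavior$attractiveness[idx] <- sample(0:spec$config$rating_max, 1)
    cohort$behavior$trustworthiness[idx] <- sample(0:spec$config$rating_max, 1)
    cohort$behavior$amount[idx] <- sample(opts, 1)
  }
  cohort$behavior$invest <- as.integer(cohort$behavior$amount > 0)
  c(cohort, list(nonserious_ids = ns_ids))
}

#' Planted biomarker effect specification
#'
#' @param name Metabolite column name.
#' @param target One of the nine decision parameter names.
#' @param slope Concentration change per parameter unit (sign sets the
#'   correlation direction).
#' @param noise_sd Gaussian noise SD on the concentration.
#' @return One-row data frame.
#' @export
planted_effect <- function(name, target, slope, noise_sd) {
  if (!target %in% PARAM_NAMES)
    stop("planted target is not a decision parameter: ", target,
         call. = FALSE)
  data.frame(name = name, target = target, slope = slope,
             noise_sd = noise_sd, stringsAsFactors = FALSE)
}

#' Planted effects calibrated to a population correlation
#'
#' Sets each effect's noise SD so the planted (parameter, metabolite)
#' pair has population Pearson correlation of magnitude `r`, given the
#' realized spread of the target parameter in `truth`.
#'
#' @param truth Truth data frame from [generate_cohort()].
#' @param targets Character vector of target parameter names (recycled
#'   over the planted columns).
#' @param r Target correlation magnitude in (0, 1).
#' @param n_planted Number of planted columns.
#' @param negative Logical; plant negative correlations (the default
#'   direction for attractiveness-weight-linked metabolites).
#' @return Data frame of [planted_effect()] rows.
#' @export
planted_effects_for_r <- function(truth, targets = c("w_a", "w_t", "gamma"),
                                  r = 0.6, n_planted = 10, negative = TRUE) {
  stopifnot(r > 0, r < 1)
  targets <- rep_len(targets, n_planted)
  out <- lapply(seq_len(n_planted), function(k) {
    tg <- targets[k]
    sdp <- sd(truth[[tg]])
    slope <- (if (negative) -1 else 1) * 1  # unit slope; noise sets r
    noise <- abs(slope) * sdp * sqrt(1 / r^2 - 1)
    planted_effect(sprintf("planted_%02d_%s", k, tg), tg, slope, noise)
  })
  do.call(rbind, out)
}

#' Generate a participants-by-metabolites biomarker table
#'
#' Planted columns are linear in a true decision parameter plus
#' Gaussian noise, shifted to be nonnegative (shifting preserves the
#' correlation); null columns are independent of everything. With the
#' defaults the table has 85 columns, emulating a plasma metabolomics
#' panel.
#'
#' @param truth Truth data frame from [generate_cohort()].
#' @param planted Data frame of [planted_effect()] rows (may be empty).
#' @param n_null Independent null columns; `nrow(planted) + n_null`
#'   metabolites in total (default total 85).
#' @param seed Integer seed.
#' @param null_mean,null_sd Location/spread of the null columns.
#' @return Data frame `participant_id` + one numeric column per
#'   metabolite, all finite and nonnegative.
#' @export
generate_biomarkers <- function(truth, planted = NULL, n_null = 75,
                                seed = 1L, null_mean = 10, null_sd = 2) {
  set.seed(seed)
  n <- nrow(truth)
  out <- data.frame(participant_id = truth$participant_id)
  if (!is.null(planted) && nrow(planted)) {
    for (k in seq_len(nrow(planted))) {
      pe <- planted[k, ]
      if (!pe$target %in% names(truth))
        stop("planted target is not a decision parameter: ", pe$target,
             call. = FALSE)
      x <- pe$slope * truth[[pe$target]] + rnorm(n, 0, pe$noise_sd)
      out[[pe$name]] <- x - min(x)  # nonnegative shift, correlation intact
    }
  }
  for (k in seq_len(n_null)) {
    x <- rnorm(n, null_mean, null_sd)
    out[[sprintf("null_%02d", k)]] <- pmax(x - min(0, min(x)), 0)
  }
  out
}
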