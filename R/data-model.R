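#' @useDynLib trustbayes, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom rgamma sd cor cor.test wilcox.test
#'   t.test p.adjust dnorm dgamma plogis quantile hclust as.dist dist
#'   complete.cases setNames
#' @importFrom utils read.csv write.csv write.table head packageVersion
NULL

# Canonical parameter order used everywhere (CSV columns, draw matrices).
PARAM_NAMES <- c("w_o", "w_a", "w_t", "sigma_e", "beta", "gamma",
                 "s", "c", "sigma_m")

#' Participant decision parameters
#'
#' Bundles the nine participant-specific parameters of the trust-game
#' decision model: the evaluation weights (`w_o` basal, `w_a`
#' attractiveness, `w_t` trustworthiness), the evaluation noise scale
#' `sigma_e`, the investment sigmoid steepness `beta` and threshold
#' `gamma`, and the amount policy slope `s` (JPY per evaluation unit),
#' intercept `c` (JPY) and noise scale `sigma_m` (JPY).
#'
#' @param w_o,w_a,w_t Evaluation weights (basal, attractiveness,
#'   trustworthiness).
#' @param sigma_e Evaluation noise standard deviation, > 0.
#' @param beta Sigmoid steepness, > 0.
#' @param gamma Sigmoid threshold (evaluation units).
#' @param s,c Amount slope (JPY per evaluation unit) and intercept (JPY).
#' @param sigma_m Amount noise standard deviation (JPY), > 0.
#' @return Named numeric vector of length 9 with class
#'   `"participant_params"`.
#' @export
participant_params <- function(w_o = 0, w_a = 0, w_t = 0, sigma_e = 0.5,
                               beta = 5, gamma = 1, s = 100, c = 100,
                               sigma_m = 100) {
  p <- c(w_o = w_o, w_a = w_a, w_t = w_t, sigma_e = sigma_e, beta = beta,
         gamma = gamma, s = s, c = c, sigma_m = sigma_m)
  validate_params(p)
  class(p) <- c("participant_params", "numeric")
  p
}

validate_params <- function(p) {
  stopifnot(is.numeric(p), all(PARAM_NAMES %in% names(p)))
  if (!all(is.finite(p[PARAM_NAMES])))
    stop("participant parameters must be finite", call. = FALSE)
  bad <- c("sigma_e", "beta", "sigma_m")[p[c("sigma_e", "beta", "sigma_m")] <= 0]
  if (length(bad))
    stop("parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(p)
}

#' Prior hyperparameters for the decision model
#'
#' Defaults are the model's reference prior: standard-normal priors on
#' the three evaluation weights, Gamma(shape 5, scale 1) on `beta`,
#' N(1, 1) on `gamma`, half-normal(0.5) on `sigma_e`, N(100, 100) on
#' `s` and `c`, and half-normal(100) on `sigma_m`. Normal `*_scale`
#' entries are standard deviations by default; set
#' `scales_are_variances = TRUE` to reinterpret them as variances.
#'
#' @param w_a_mean,w_a_scale,w_t_mean,w_t_scale,w_o_mean,w_o_scale
#'   Normal prior location/scale for the evaluation weights.
#' @param beta_shape,beta_scale Gamma prior shape and scale for `beta`.
#' @param gamma_mean,gamma_scale Normal prior for the sigmoid threshold.
#' @param sigma_e_scale Half-normal scale for the evaluation noise SD.
#' @param s_mean,s_scale,c_mean,c_scale Normal priors for the amount
#'   slope and intercept (JPY scale).
#' @param sigma_m_scale Half-normal scale for the amount noise SD (JPY).
#' @param scales_are_variances Interpret normal scale entries as
#'   variances instead of standard deviations.
#' @return List with class `"hyper_priors"`.
#' @export
hyper_priors <- function(w_a_mean = 0, w_a_scale = 1,
                         w_t_mean = 0, w_t_scale = 1,
                         w_o_mean = 0, w_o_scale = 1,
                         beta_shape = 5, beta_scale = 1,
                         gamma_mean = 1, gamma_scale = 1,
                         sigma_e_scale = 0.5,
                         s_mean = 100, s_scale = 100,
                         c_mean = 100, c_scale = 100,
                         sigma_m_scale = 100,
                         scales_are_variances = FALSE) {
  h <- list(w_a_mean = w_a_mean, w_a_scale = w_a_scale,
            w_t_mean = w_t_mean, w_t_scale = w_t_scale,
            w_o_mean = w_o_mean, w_o_scale = w_o_scale,
            beta_shape = beta_shape, beta_scale = beta_scale,
            gamma_mean = gamma_mean, gamma_scale = gamma_scale,
            sigma_e_scale = sigma_e_scale,
            s_mean = s_mean, s_scale = s_scale,
            c_mean = c_mean, c_scale = c_scale,
            sigma_m_scale = sigma_m_scale)
  scales <- grepl("_(scale|shape)$", names(h))
  if (any(unlist(h[scales]) <= 0))
    stop("all prior scale/shape hyperparameters must be strictly positive",
         call. = FALSE)
  if (scales_are_variances) {
    sdify <- c("w_a_scale", "w_t_scale", "w_o_scale", "gamma_scale",
               "s_scale", "c_scale", "sigma_e_scale", "sigma_m_scale")
    h[sdify] <- lapply(h[sdify], sqrt)
  }
  structure(h, class = "hyper_priors")
}

#' Model response-scale configuration
#'
#' @param amount_max Maximum investable amount (JPY).
#' @param amount_step Amount quantization step (JPY).
#' @param rating_max Maximum rating on the 0-based discrete scale.
#' @return List with the amount/rating grids; 14 amount options and the
#'   0--9 rating scale by default.
#' @export
model_config <- function(amount_max = 1300, amount_step = 100,
                         rating_max = 9) {
  if (amount_max %% amount_step != 0)
    stop("amount_max must be a multiple of amount_step", call. = FALSE)
  list(amount_max = amount_max, amount_step = amount_step,
       rating_max = rating_max,
       amount_options = c(0, seq(amount_step, amount_max, by = amount_step)))
}

BEHAVIOR_COLS <- c("participant_id", "partner_id", "attractiveness",
                   "trustworthiness", "amount")

#' Validate a long-format behavior table
#'
#' Checks the trial-level invariants: integer ratings in `[0, rating_max]`,
#' amounts on the 100-JPY grid in `[0, amount_max]`, unique partners per
#' participant, and a common partner set across participants. Derives the
#' binary invest indicator `invest = amount > 0`.
#'
#' @param df Data frame with columns `participant_id`, `partner_id`,
#'   `attractiveness`, `trustworthiness`, `amount` (and optionally
#'   `group`).
#' @param config Output of [model_config()].
#' @return The validated data frame with an `invest` column, ordered by
#'   participant then partner.
#' @export
validate_behavior <- function(df, config = model_config()) {
  missing_cols <- setdiff(BEHAVIOR_COLS, names(df))
  if (length(missing_cols))
    stop("behavior table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num <- c("attractiveness", "trustworthiness", "amount")
  bad_rows <- which(!complete.cases(df[num]) |
                      !vapply(seq_len(nrow(df)),
                              function(i) all(is.finite(as.numeric(df[i, num]))),
                              logical(1)))
  if (length(bad_rows))
    stop("malformed behavior row(s): ", paste(head(bad_rows, 10), collapse = ", "),
         call. = FALSE)

  cell_errors <- character(0)
  check <- function(col, ok) {
    bad <- which(!ok)
    if (length(bad))
      cell_errors <<- c(cell_errors,
                        sprintf("row %d, %s = %s", bad, col,
                                format(df[[col]][bad])))
  }
  rate_ok <- function(x) x == round(x) & x >= 0 & x <= config$rating_max
  check("attractiveness", rate_ok(df$attractiveness))
  check("trustworthiness", rate_ok(df$trustworthiness))
  check("amount", df$amount %in% config$amount_options)
  if (length(cell_errors))
    stop("behavior table validation failed:\n  ",
         paste(head(cell_errors, 20), collapse = "\n  "), call. = FALSE)

  dup <- duplicated(df[c("participant_id", "partner_id")])
  if (any(dup))
    stop("duplicated (participant, partner) pair(s) at row(s): ",
         paste(head(which(dup), 10), collapse = ", "), call. = FALSE)
  partner_sets <- tapply(as.character(df$partner_id), df$participant_id,
                         function(x) paste(sort(x), collapse = "\r"))
  if (length(unique(partner_sets)) > 1L)
    stop("participants do not share a common partner set", call. = FALSE)

  df$invest <- as.integer(df$amount > 0)
  df <- df[order(df$participant_id, df$partner_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a behavioral trial table from delimited text
#'
#' One row per participant-partner interaction. The invest indicator is
#' derived, not read: a trial counts as invested exactly when its amount
#' is positive.
#'
#' @param path CSV path (configurable delimiter).
#' @param sep Field delimiter.
#' @param config Output of [model_config()].
#' @return Validated long-format data frame (see [validate_behavior()]).
#' @export
read_behavior_table <- function(path, sep = ",", config = model_config()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  validate_behavior(df, config)
}

#' Write a behavior table to CSV
#' @param df Validated behavior table.
#' @param path Output path.
#' @export
write_behavior_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a participants-by-metabolites biomarker table
#'
#' First column identifies the participant; every remaining column is a
#' numeric metabolite concentration. Empty cells become `NA` and are
#' excluded pairwise downstream, never treated as zero.
#'
#' @param path CSV path.
#' @param behavior Optional validated behavior table; when given, the
#'   participant overlap is reported and mismatches raise a warning.
#' @return Data frame with `participant_id` plus metabolite columns, and
#'   attribute `"overlap"` when `behavior` was supplied.
#' @export
read_biomarker_table <- function(path, behavior = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  names(df)[1] <- "participant_id"
  if (anyDuplicated(df$participant_id))
    stop("duplicated participant_id in biomarker table: ",
         paste(unique(df$participant_id[duplicated(df$participant_id)]),
               collapse = ", "), call. = FALSE)
  for (col in names(df)[-1]) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      v[v %in% c("", "NA")] <- NA
      suppressWarnings(v <- as.numeric(v))
    }
    df[[col]] <- v
  }
  if (!is.null(behavior)) {
    b_ids <- unique(as.character(behavior$participant_id))
    m_ids <- as.character(df$participant_id)
    only_b <- setdiff(b_ids, m_ids)
    only_m <- setdiff(m_ids, b_ids)
    if (length(only_b) || length(only_m))
      warning(sprintf(
        "participant mismatch: %d behavioral-only, %d biomarker-only; %d shared",
        length(only_b), length(only_m), length(intersect(b_ids, m_ids))),
        call. = FALSE)
    attr(df, "overlap") <- list(shared = intersect(b_ids, m_ids),
                                behavior_only = only_b,
                                biomarker_only = only_m)
  }
  df
}

#' Write per-participant parameter estimates to CSV
#'
#' One row per participant with the nine named parameter columns; the
#' output round-trips losslessly through [read_params_table()].
#'
#' @param estimates Named list of `participant_params` (names are
#'   participant ids) or a data frame with `participant_id` plus the
#'   nine parameter columns.
#' @param path Output path.
#' @export
write_params <- function(estimates, path) {
  df <- as_params_df(estimates)
  if (nrow(df) == 0) stop("no parameter estimates to write", call. = FALSE)
  for (i in seq_len(nrow(df)))
    validate_params(setNames(as.numeric(df[i, PARAM_NAMES]), PARAM_NAMES))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop("cannot open path for writing: ", path, call. = FALSE)
  on.exit(close(con))
  # full precision so the round-trip is exact
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

as_params_df <- function(estimates) {
  if (is.data.frame(estimates)) {
    stopifnot(all(c("participant_id", PARAM_NAMES) %in% names(estimates)))
    return(estimates[c("participant_id", PARAM_NAMES)])
  }
  if (!length(estimates)) return(data.frame())
  stopifnot(!is.null(names(estimates)))
  rows <- lapply(names(estimates), function(id) {
    p <- estimates[[id]]
    cbind(data.frame(participant_id = id),
          as.data.frame(as.list(p[PARAM_NAMES])))
  })
  do.call(rbind, rows)
}

#' Read a parameter table written by [write_params()]
#' @param path CSV path.
#' @return Data frame with `participant_id` and the nine parameters.
#' @export
read_params_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("participant_id", PARAM_NAMES), names(df))
  if (length(missing_cols))
    stop("parameter table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df
}

#' Split a behavior table into per-participant trial blocks
#' @param behavior Validated behavior table.
#' @return Named list of per-participant data frames.
#' @export
split_participants <- function(behavior) {
  split(behavior, behavior$participant_id)
}

participant_groups <- function(behavior) {
  g <- unique(behavior[c("participant_id", "group")])
  setNames(as.character(g$group), as.character(g$participant_id))
}
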