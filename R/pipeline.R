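#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end synthetic pipeline:
#' cohort generation, entropy QC, per-participant MCMC fits,
#' cross-validation, and the two biomarker association screens.
#'
#' @param out_dir Output directory (created if missing).
#' @param spec [cohort_spec()].
#' @param hyper [hyper_priors()].
#' @param mcmc [mcmc_settings()] for the full-data fits.
#' @param qc_threshold,qc_base,qc_channels Entropy QC settings.
#' @param nonserious_fraction Fraction of constant responders planted
#'   into the cohort (exercises the QC stage).
#' @param n_train Training partners per participant for CV; `NULL`
#'   means `floor(3/4 * n_partners)`.
#' @param cv_mcmc [mcmc_settings()] for the CV refits.
#' @param n_planted,planted_r,n_null Biomarker screen plant settings
#'   (total metabolite columns = `n_planted + n_null`, default 85).
#' @param fdr_level BH-FDR significance level.
#' @param seed Global seed; every stage derives its randomness from it.
#' @param max_fit Optional cap on the number of retained participants
#'   fitted (smallest ids first); `NULL` fits everyone.
#' @return List with class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = "results/pipeline",
                            spec = cohort_spec(),
                            hyper = hyper_priors(),
                            mcmc = mcmc_settings(),
                            qc_threshold = 1.5, qc_base = 2,
                            qc_channels = "amount",
                            nonserious_fraction = 0,
                            n_train = NULL,
                            cv_mcmc = mcmc,
                            n_planted = 10, planted_r = 0.6, n_null = 75,
                            fdr_level = 0.05,
                            seed = 1L, max_fit = NULL) {
  structure(list(out_dir = out_dir, spec = spec, hyper = hyper, mcmc = mcmc,
                 qc_threshold = qc_threshold, qc_base = qc_base,
                 qc_channels = qc_channels,
                 nonserious_fraction = nonserious_fraction,
                 n_train = n_train, cv_mcmc = cv_mcmc,
                 n_planted = n_planted, planted_r = planted_r,
                 n_null = n_null, fdr_level = fdr_level,
                 seed = as.integer(seed), max_fit = max_fit),
            class = "pipeline_config")
}

#' Read pipeline configuration overrides from YAML
#'
#' Top-level keys mirror [pipeline_config()] arguments; `spec`,
#' `hyper`, `mcmc` and `cv_mcmc` entries are passed to their
#' constructors. Unknown keys are an error.
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in names(y)) {
    val <- switch(nm,
      spec = do.call(cohort_spec, y[[nm]]),
      hyper = do.call(hyper_priors, y[[nm]]),
      mcmc = do.call(mcmc_settings, y[[nm]]),
      cv_mcmc = do.call(mcmc_settings, y[[nm]]),
      y[[nm]])
    if (!nm %in% names(formals(pipeline_config)))
      stop("unknown config key: ", nm, call. = FALSE)
    args[[nm]] <- val
  }
  do.call(pipeline_config, args)
}

# deterministic per-participant seed stream below 2^31
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max %/% 2, n)
}

#' Run the full synthetic pipeline
#'
#' Stages, in order: simulate (cohort + biomarkers), qc (entropy
#' filter), fit (per-participant MCMC, MAP estimates, trace), crossval
#' (held-out prediction per participant), associate (behavior- and
#' parameter-level biomarker screens). Every artifact is written under
#' `config$out_dir`; outputs depend only on (config, seed), so a rerun
#' with the same seed reproduces them byte for byte. Per-participant
#' fits are independent; results are written in participant-id order.
#'
#' @param config [pipeline_config()].
#' @param quiet Suppress per-stage log lines.
#' @return Run manifest (list), also written as `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(config$out_dir, f)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(package_version = as.character(utils::packageVersion("trustbayes")),
                   r_version = R.version.string,
                   seed = config$seed, stages = list())

  # ---- stage 1: simulate ----
  cohort <- if (config$nonserious_fraction > 0) {
    generate_nonserious(config$spec, config$nonserious_fraction, config$seed)
  } else {
    generate_cohort(config$spec, config$seed)
  }
  planted <- if (config$n_planted > 0)
    planted_effects_for_r(cohort$truth, r = config$planted_r,
                          n_planted = config$n_planted) else NULL
  biomarkers <- generate_biomarkers(cohort$truth, planted,
                                    n_null = config$n_null,
                                    seed = config$seed + 1L)
  write_behavior_table(cohort$behavior, pth("behavior.csv"))
  write.csv(biomarkers, pth("biomarkers.csv"), row.names = FALSE)
  write.csv(cohort$truth, pth("truth.csv"), row.names = FALSE)
  say("simulate: %d participants x %d partners, %d metabolites",
      nrow(cohort$truth), config$spec$n_partners, ncol(biomarkers) - 1)
  manifest$stages$simulate <- list(participants = nrow(cohort$truth),
                                   partners = config$spec$n_partners,
                                   metabolites = ncol(biomarkers) - 1)

  # ---- stage 2: qc ----
  qc <- qc_filter(cohort$behavior, threshold = config$qc_threshold,
                  channels = config$qc_channels, base = config$qc_base)
  write.csv(qc$report, pth("qc_report.csv"), row.names = FALSE)
  retained_ids <- unique(as.character(qc$retained$participant_id))
  say("qc: %d retained, %d excluded (entropy < %.2f)",
      length(retained_ids), length(qc$excluded_ids), config$qc_threshold)
  manifest$stages$qc <- list(retained = length(retained_ids),
                             excluded = length(qc$excluded_ids))

  # ---- stage 3: fit ----
  fit_ids <- retained_ids
  if (!is.null(config$max_fit)) fit_ids <- head(fit_ids, config$max_fit)
  seeds <- derive_seeds(config$seed + 2L, length(fit_ids))
  blocks <- split_participants(qc$retained)
  fits <- list(); params_rows <- list(); trace_rows <- list()
  eval_mat <- NULL
  for (i in seq_along(fit_ids)) {
    id <- fit_ids[i]
    fit <- fit_participant(blocks[[id]], config$hyper, config$mcmc,
                           seed = seeds[i], participant_id = id)
    map <- map_estimate(fit)
    fits[[id]] <- fit
    params_rows[[id]] <- cbind(
      data.frame(participant_id = id,
                 group = as.character(blocks[[id]]$group[1])),
      as.data.frame(as.list(map[PARAM_NAMES])))
    trace_rows[[id]] <- data.frame(participant_id = id,
                                   iteration = seq_along(fit$lp_trace),
                                   log_posterior = fit$lp_trace)
    pm <- posterior_mean_evaluations(fit)
    if (is.null(eval_mat))
      eval_mat <- matrix(NA_real_, length(fit_ids), length(pm),
                         dimnames = list(fit_ids, names(pm)))
    eval_mat[id, names(pm)] <- pm
  }
  params_df <- do.call(rbind, params_rows[fit_ids])
  write_params(params_df, pth("params.csv"))
  write.csv(do.call(rbind, trace_rows[fit_ids]), pth("trace.csv"),
            row.names = FALSE)
  write.csv(data.frame(participant_id = rownames(eval_mat), eval_mat,
                       check.names = FALSE),
            pth("evaluations.csv"), row.names = FALSE)
  conv <- vapply(fits, function(f) check_convergence(f)$passes, TRUE)
  say("fit: %d participants, %d/%d converged traces",
      length(fit_ids), sum(conv), length(conv))
  manifest$stages$fit <- list(fitted = length(fit_ids),
                              converged = sum(conv))

  # ---- stage 4: crossval ----
  np <- config$spec$n_partners
  n_train <- config$n_train %||% floor(3 * np / 4)
  cv_rows <- lapply(seq_along(fit_ids), function(i) {
    cv <- cross_validate(blocks[[fit_ids[i]]], config$hyper,
                         n_train = n_train, n_test = np - n_train,
                         seed = seeds[i] + 1L, mcmc = config$cv_mcmc)
    data.frame(participant_id = fit_ids[i],
               invest_accuracy = cv$invest_accuracy,
               amount_r2 = cv$amount_r2)
  })
  cv_df <- do.call(rbind, cv_rows)
  write.csv(cv_df, pth("cv.csv"), row.names = FALSE)
  say("crossval: mean invest accuracy %.3f, mean amount r2 %.3f",
      mean(cv_df$invest_accuracy), mean(cv_df$amount_r2, na.rm = TRUE))
  manifest$stages$crossval <-
    list(participants = nrow(cv_df),
         mean_invest_accuracy = mean(cv_df$invest_accuracy),
         mean_amount_r2 = mean(cv_df$amount_r2, na.rm = TRUE))

  # ---- stage 5: associate ----
  behav <- behavior_summaries(qc$retained)
  assoc_b <- correlate(behav, biomarkers, method = "spearman",
                       fdr_level = config$fdr_level)
  assoc_p <- correlate(params_df, biomarkers, method = "pearson",
                       fdr_level = config$fdr_level)
  write.csv(assoc_b, pth("associations_behavior.csv"), row.names = FALSE)
  write.csv(assoc_p, pth("associations_params.csv"), row.names = FALSE)
  say("associate: %d/%d behavior pairs, %d/%d parameter pairs significant",
      sum(assoc_b$significant), nrow(assoc_b),
      sum(assoc_p$significant), nrow(assoc_p))
  manifest$stages$associate <-
    list(behavior_pairs = nrow(assoc_b),
         behavior_significant = sum(assoc_b$significant),
         param_pairs = nrow(assoc_p),
         param_significant = sum(assoc_p$significant))

  manifest$elapsed_seconds <- round(proc.time()[["elapsed"]] - t0, 2)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
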