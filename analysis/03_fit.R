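#!/usr/bin/env Rscript
# Stage 3 -- participant-level Bayesian fits.
#
# Samples each retained participant's joint posterior over the nine
# decision parameters and the per-trial latent evaluations
# (slice-within-Gibbs, 2000 burn-in + 4000 kept draws), records the
# log-posterior trace, extracts MAP point estimates (marginal-density
# argmax over kept draws) with posterior means as the secondary
# estimator, and exports posterior-mean latent evaluations for the
# group-contrast stage.

suppressPackageStartupMessages(library(trustbayes))
seed <- 20260103L
out <- "results/analysis"
behavior <- read_behavior_table(file.path(out, "behavior_retained.csv"))
blocks <- split_participants(behavior)
ids <- names(blocks)
mc <- mcmc_settings(burnin = 2000, draws = 4000)
set.seed(seed)
fit_seeds <- sample.int(2^30, length(ids))

params_rows <- trace_rows <- pmean_rows <- vector("list", length(ids))
eval_mat <- NULL
conv <- logical(length(ids))
t0 <- proc.time()[["elapsed"]]
for (i in seq_along(ids)) {
  fit <- fit_participant(blocks[[ids[i]]], mcmc = mc, seed = fit_seeds[i],
                         participant_id = ids[i])
  map <- map_estimate(fit)
  conv[i] <- check_convergence(fit)$passes
  params_rows[[i]] <- cbind(
    data.frame(participant_id = ids[i],
               group = as.character(blocks[[ids[i]]]$group[1])),
    as.data.frame(as.list(map[c("w_o", "w_a", "w_t", "sigma_e", "beta",
                                "gamma", "s", "c", "sigma_m")])))
  pmean_rows[[i]] <- cbind(
    data.frame(participant_id = ids[i]),
    as.data.frame(as.list(attr(map, "posterior_mean"))))
  trace_rows[[i]] <- data.frame(participant_id = ids[i],
                                iteration = seq_along(fit$lp_trace),
                                log_posterior = fit$lp_trace)
  pm <- posterior_mean_evaluations(fit)
  if (is.null(eval_mat))
    eval_mat <- matrix(NA_real_, length(ids), length(pm),
                       dimnames = list(ids, names(pm)))
  eval_mat[ids[i], names(pm)] <- pm
}
message(sprintf("fitted %d participants in %.1f min; %d/%d traces pass the drift check",
                length(ids), (proc.time()[["elapsed"]] - t0) / 60,
                sum(conv), length(conv)))

write_params(do.call(rbind, params_rows), file.path(out, "params_map.csv"))
write.csv(do.call(rbind, pmean_rows), file.path(out, "params_pmean.csv"),
          row.names = FALSE)
write.csv(do.call(rbind, trace_rows), file.path(out, "trace.csv"),
          row.names = FALSE)
write.csv(data.frame(participant_id = rownames(eval_mat), eval_mat,
                     check.names = FALSE),
          file.path(out, "evaluations_pmean.csv"), row.names = FALSE)
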