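#!/usr/bin/env Rscript
# Stage 5 -- group contrasts and biomarker screens.
#
# (a) Welch t-tests of each estimated decision parameter between groups;
# (b) per-partner Mann-Whitney tests on posterior-mean latent
#     evaluations E_ij (HC vs MDD), with the count of partners
#     significant at p < 0.05;
# (c) Spearman screen of behavioral averages vs metabolites and Pearson
#     screen of estimated parameters vs metabolites, both BH-FDR
#     corrected at q < 0.05, with average-linkage clustering of the
#     parameter screen for heatmap plotting.

suppressPackageStartupMessages(library(trustbayes))
out <- "results/analysis"
behavior <- read_behavior_table(file.path(out, "behavior_retained.csv"))
params <- read_params_table(file.path(out, "params_map.csv"))
groups <- unique(behavior[c("participant_id", "group")])
params$group <- groups$group[match(params$participant_id,
                                   groups$participant_id)]
biomarkers <- read_biomarker_table(file.path(out, "biomarkers.csv"),
                                   behavior = behavior)

# (a) parameter group contrasts
par_names <- c("w_o", "w_a", "w_t", "sigma_e", "beta", "gamma",
               "s", "c", "sigma_m")
gc_rows <- lapply(par_names, function(p) {
  gt <- group_compare(params[[p]], params$group, test = "welch_t")
  data.frame(parameter = p, statistic = gt$statistic, p = gt$p_value)
})
gc_df <- do.call(rbind, gc_rows)
gc_df$q <- bh_fdr(gc_df$p)
write.csv(gc_df, file.path(out, "param_group_tests.csv"), row.names = FALSE)
message(sprintf("parameter group contrasts: %d/%d significant at q < 0.05",
                sum(gc_df$q < 0.05), nrow(gc_df)))

# (b) per-partner evaluation contrasts
evals <- read.csv(file.path(out, "evaluations_pmean.csv"),
                  check.names = FALSE)
em <- as.matrix(evals[, -1])
rownames(em) <- evals$participant_id
g <- setNames(groups$group, groups$participant_id)
pp <- per_partner_evaluation_test(em, g)
write.csv(pp$per_partner, file.path(out, "per_partner_tests.csv"),
          row.names = FALSE)
message(sprintf("per-partner evaluation tests: %d of %d partners at p < 0.05",
                pp$n_significant, pp$n_partners))

# (c) biomarker screens
behav <- behavior_summaries(behavior)
scr_b <- correlate(behav, biomarkers, method = "spearman")
scr_p <- correlate(params[c("participant_id", par_names)], biomarkers,
                   method = "pearson")
write.csv(scr_b, file.path(out, "screen_behavior.csv"), row.names = FALSE)
write.csv(scr_p, file.path(out, "screen_params.csv"), row.names = FALSE)
invisible(cluster_heatmap_export(scr_p,
                                 file.path(out, "screen_params_clustered.csv")))
message(sprintf(
  "screens: behavior %d/%d significant, parameters %d/%d significant (q < 0.05)",
  sum(scr_b$significant), nrow(scr_b),
  sum(scr_p$significant), nrow(scr_p)))
sig <- scr_p[scr_p$significant, c("x_name", "y_name", "r", "q")]
if (nrow(sig)) print(sig, row.names = FALSE)
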