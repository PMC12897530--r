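#!/usr/bin/env Rscript
# Stage 4 -- cross-validated prediction.
#
# For every retained participant: random 30/10 partner split (the 3/4
# rule at 40 partners), refit on the training partners, then score the
# MAP model on the held-out partners -- invest decisions classified at
# probability 0.5 (accuracy) and amounts by squared Pearson correlation
# between predicted expected amounts and observations.

suppressPackageStartupMessages(library(trustbayes))
seed <- 20260104L
out <- "results/analysis"
behavior <- read_behavior_table(file.path(out, "behavior_retained.csv"))
blocks <- split_participants(behavior)
ids <- names(blocks)
set.seed(seed)
cv_seeds <- sample.int(2^30, length(ids))
mc <- mcmc_settings(burnin = 1000, draws = 1500, thin = 2)

rows <- lapply(seq_along(ids), function(i) {
  cv <- cross_validate(blocks[[ids[i]]], seed = cv_seeds[i], mcmc = mc)
  data.frame(participant_id = ids[i],
             group = as.character(blocks[[ids[i]]]$group[1]),
             n_train = length(cv$train_partner_ids),
             n_test = length(cv$test_partner_ids),
             invest_accuracy = cv$invest_accuracy,
             amount_r2 = cv$amount_r2)
})
cv_df <- do.call(rbind, rows)
write.csv(cv_df, file.path(out, "cv.csv"), row.names = FALSE)
message(sprintf(
  "cross-validation over %d participants: invest accuracy %.3f +/- %.3f, amount r2 %.3f +/- %.3f",
  nrow(cv_df), mean(cv_df$invest_accuracy), sd(cv_df$invest_accuracy),
  mean(cv_df$amount_r2, na.rm = TRUE), sd(cv_df$amount_r2, na.rm = TRUE)))
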