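#!/usr/bin/env Rscript
# Stage 1 -- simulate the study cohort.
#
# Generates a synthetic trust-game cohort at the reference design (38
# healthy controls + 38 MDD, 40 shared photographed partners, 0-9
# ratings, 0-1300 JPY amounts in 100-JPY steps) with a 10% planted
# non-serious fraction for the QC stage to find, plus an 85-column
# biomarker table (10 planted effects at |r| ~ 0.6 against true decision
# parameters, 75 nulls).

suppressPackageStartupMessages(library(trustbayes))
seed <- 20260101L
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- cohort_spec()  # the reference design
cohort <- generate_nonserious(spec, fraction = 0.10, seed = seed)
planted <- planted_effects_for_r(cohort$truth, r = 0.6, n_planted = 10)
biomarkers <- generate_biomarkers(cohort$truth, planted, n_null = 75,
                                  seed = seed + 1L)

write_behavior_table(cohort$behavior, file.path(out, "behavior.csv"))
write.csv(biomarkers, file.path(out, "biomarkers.csv"), row.names = FALSE)
write.csv(cohort$truth, file.path(out, "truth.csv"), row.names = FALSE)
write.csv(data.frame(participant_id = rownames(cohort$evaluations),
                     cohort$evaluations, check.names = FALSE),
          file.path(out, "true_evaluations.csv"), row.names = FALSE)
write.csv(planted, file.path(out, "planted_effects.csv"), row.names = FALSE)

message(sprintf(
  "simulated %d participants x %d partners (%d non-serious planted), %d metabolites",
  nrow(cohort$truth), spec$n_partners, length(cohort$nonserious_ids),
  ncol(biomarkers) - 1))
message(sprintf("invest rate %.2f, mean amount %.0f JPY",
                mean(cohort$behavior$invest),
                mean(cohort$behavior$amount)))
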