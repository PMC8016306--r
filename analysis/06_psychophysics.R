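#!/usr/bin/env Rscript
# Psychophysical scoring of a synthetic same-different session: the four
# experimental tasks (passive same / inverse / direct force-rate, active same
# force-rate) simulated with a differencing observer whose sensitivity rises
# across tasks, then scored with percent correct, 75% threshold flags, pooled
# and per-pair d', and pairwise condition comparisons.

library(tactillusion)
dir.create("results", showWarnings = FALSE)

spec <- session_spec(participants = 10, seed = 11)
trials <- gen_session(spec)
write.csv(trials, "results/psycho_trials.csv", row.names = FALSE)

res <- run_experiment3(trials)
write.csv(res$report$conditions, "results/psycho_conditions.csv",
          row.names = FALSE)
write.csv(res$report$pairs, "results/psycho_pairs.csv", row.names = FALSE)
write.csv(res$comparisons, "results/psycho_comparisons.csv", row.names = FALSE)

cat("per-condition summary:\n")
print(res$report$conditions[, c("condition", "percent_correct",
                                "above_threshold", "dprime_pooled",
                                "dprime_pair_mean")])
cat("\npairwise condition comparisons (participant-level percent correct):\n")
print(res$comparisons)
cat(sprintf("\ngenerating observer sensitivities: %s\n",
            paste(sprintf("%s=%.1f", spec$conditions$condition,
                          spec$conditions$dprime), collapse = ", ")))
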