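#!/usr/bin/env Rscript
# Stage 5 — validation against ground truth.
#
# Two experiments that only synthetic data makes possible: (a) parameter
# recovery of the ICC over a grid of true values and censoring levels,
# with credible-interval coverage; (b) the cost of the LOD/2 substitution
# shortcut for nondetects, measured as bias in the within-subject variance
# against the censored likelihood.

library(metabicc)

out <- "results/recovery"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20140325

rec <- run_recovery_suite(n_features = 50, icc_grid = c(0.2, 0.5, 0.8),
                          cens_grid = c(0, 0.2, 0.4),
                          mcmc = mcmc_settings(2000, 4), master_seed = seed)
write.csv(rec$per_feature, file.path(out, "recovery_per_feature.csv"),
          row.names = FALSE)
write.csv(rec$summary, file.path(out, "recovery_summary.csv"),
          row.names = FALSE)
cat("ICC recovery (mean absolute error / CrI coverage per cell):\n")
print(rec$summary)
cat(sprintf("pooled: MAE %.3f, coverage %.2f\n",
            mean(rec$per_feature$abs_err), mean(rec$per_feature$covered)))

ex <- substitution_bias_experiment(n_reps = 20, sigma_sq = c(1, 1, 0.25),
                                   detection = 0.6,
                                   mcmc = mcmc_settings(2000, 4),
                                   master_seed = seed)
write.csv(ex, file.path(out, "substitution_bias.csv"), row.names = FALSE)
cat(sprintf(
  "LOD/2 substitution at 40%% censoring: sigma1_sq bias %+.3f (vs %+.3f censored); censored fit closer to truth in %d/20 replicates\n",
  mean(ex$bias_substituted), mean(ex$bias_censored),
  sum(ex$censored_wins)))
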