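#!/usr/bin/env Rscript
# Stage 4 — estimand summaries, duplicate collapse, grouping and
# centre stratification.
#
# Collapses duplicate annotations to one result per compound (highest
# posterior-median ICC wins), classifies repeatability, summarizes ICCs by
# chemical class, compares the adjusted/two-level variants to the main
# model, and refits two-level models within each centre.

library(metabicc)

out <- "results/summaries"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20140325

un <- read.csv("results/fits/icc_unadjusted.csv", stringsAsFactors = FALSE)
ad <- read.csv("results/fits/icc_adjusted.csv", stringsAsFactors = FALSE)
two <- read.csv("results/fits/icc_two_level.csv", stringsAsFactors = FALSE)
ann <- read.csv("results/qc/annotation_map.csv", stringsAsFactors = FALSE)
truth <- read.csv("results/sim/ground_truth.csv", stringsAsFactors = FALSE)

main <- un[un$estimand == "three_level" & un$status == "ok", ]
wic <- un[un$estimand == "within_center", ]
cat(sprintf("median ICC: %.3f (three-level), %.3f (within-centre), %.3f (adjusted)\n",
            median(main$icc), median(wic$icc, na.rm = TRUE),
            median(ad$icc[ad$estimand == "three_level"], na.rm = TRUE)))
cat(sprintf("two-level: %.3f (log scale), %.3f (data scale)\n",
            median(two$icc[two$estimand == "two_level_log"], na.rm = TRUE),
            median(two$icc[two$estimand == "two_level_datascale"],
                   na.rm = TRUE)))
cat("repeatability classes:\n")
print(table(main$class))
cat(sprintf("recovery vs truth: cor %.3f, mean |error| %.3f\n",
            cor(main$icc, truth$icc[match(main$feature_id,
                                          truth$feature_id)]),
            mean(abs(main$icc - truth$icc[match(main$feature_id,
                                                truth$feature_id)]))))

## per-compound results: collapse duplicate annotations
cmp <- collapse_duplicates(main, ann)
write.csv(cmp, file.path(out, "icc_per_compound.csv"), row.names = FALSE)
cat(sprintf("%d fitted features -> %d unique compounds (%d duplicates dropped)\n",
            nrow(main), nrow(cmp), nrow(attr(cmp, "dropped"))))

## class summaries (classes from the synthetic annotation database)
grouping <- unique(ann[, c("feature_id", "class")])
names(grouping)[2] <- "group"
cls <- summarize_groups(main, grouping, min_group_size = 7)
write.csv(cls, file.path(out, "class_summaries.csv"), row.names = FALSE)
cat("class medians:\n")
print(cls[, c("group", "n", "median_icc", "iqr")])

## centre-stratified two-level sensitivity analysis
tab <- read_feature_table("results/qc/filtered_table.csv",
                          "results/qc/filtered_info.csv")
metadata <- read.csv("results/sim/sample_metadata.csv",
                     stringsAsFactors = FALSE)
strat <- stratify_by_center(tab, metadata, mcmc = mcmc_settings(2000, 2),
                            master_seed = seed)
write.csv(strat, file.path(out, "icc_by_center.csv"), row.names = FALSE)
cat("per-centre median ICC:\n")
print(round(tapply(strat$icc, strat$center_id, median, na.rm = TRUE), 3))
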