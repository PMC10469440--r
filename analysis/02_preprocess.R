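#!/usr/bin/env Rscript
# Stage 2 — feature-level quality control and annotation.
#
# Applies the two feature filters in study order (blank filter, then the
# 40% detection filter), computes per-feature limits of detection, and
# matches features to a synthetic annotation database by mass (+/-10 ppm)
# and retention time (+/-0.15 min). The blank injections and the database
# are generated here: a random third of the features are spiked into all
# blanks (half of them below the 5-fold threshold, so they are removed),
# and the database lists plausible compounds at the simulated features'
# masses, some shared by two features so that duplicate collapse has work
# to do downstream.

library(metabicc)

sim_dir <- "results/sim"
out <- "results/qc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(7)

tab <- read_feature_table(file.path(sim_dir, "feature_table.csv"),
                          file.path(sim_dir, "feature_info.csv"))
nf <- ncol(tab$intensities)

## blank injections: background features sit in every blank; true signals
## appear in none
n_blank <- 6
blank <- matrix(NA_real_, n_blank, nf,
                dimnames = list(sprintf("BLK%02d", 1:n_blank),
                                colnames(tab$intensities)))
bg <- sample(nf, round(nf / 3))
weak <- bg[seq_len(length(bg) %/% 2)] # sample signal < 5x blank: removed
for (f in bg) {
  samp_med <- median(tab$intensities[, f], na.rm = TRUE)
  level <- if (f %in% weak) samp_med / 3 else samp_med / 8
  blank[, f] <- level * exp(rnorm(n_blank, 0, 0.1))
}
blank_tab <- feature_table(blank, tab$features)

filtered <- blank_filter(tab, blank_tab, fold = 5)
write.csv(attr(filtered, "report"), file.path(out, "blank_filter_report.csv"),
          row.names = FALSE)
cat(sprintf("blank filter: %d features -> %d (removed %d background)\n",
            nf, ncol(filtered$intensities),
            nf - ncol(filtered$intensities)))

filtered <- detection_filter(filtered, min_rate = 0.40)
write.csv(attr(filtered, "report"),
          file.path(out, "detection_filter_report.csv"), row.names = FALSE)
cat(sprintf("detection filter (>=40%%): -> %d features\n",
            ncol(filtered$intensities)))

qc <- compute_lod(filtered)
write.csv(qc, file.path(out, "feature_qc.csv"), row.names = FALSE)
cat(sprintf("LODs span %.3g - %.3g (lowest detected value per feature)\n",
            min(qc$lod), max(qc$lod)))

## synthetic annotation database (labelled synthetic: names are invented)
fi <- filtered$features
n_db <- nrow(fi)
dup <- sample(n_db, round(n_db / 8)) # compounds shared by two features
name_of <- sprintf("compound_%03d", seq_len(n_db))
for (d in dup) name_of[d] <- name_of[(d %% n_db) + 1]
db <- data.frame(
  name = name_of,
  mass = fi$mass * (1 + runif(n_db, -5e-6, 5e-6)), # within 5 ppm
  rt = fi$rt + runif(n_db, -0.05, 0.05),
  class = sample(c("glycerophospholipid", "phosphatidylcholine",
                   "O-acylcarnitine", "amino acid", "steroid"),
                 n_db, replace = TRUE),
  stringsAsFactors = FALSE
)
write.csv(db, file.path(out, "annotation_db_synthetic.csv"),
          row.names = FALSE)

ann <- annotate_features(filtered, db, ppm_tol = 10, rt_tol = 0.15)
write.csv(ann, file.path(out, "annotation_map.csv"), row.names = FALSE)
cat(sprintf("annotation: %d features matched to %d compound names\n",
            length(unique(ann$feature_id)), length(unique(ann$name))))

## serialized filtered table for the model stage
df <- data.frame(sample_id = rownames(filtered$intensities),
                 filtered$intensities, check.names = FALSE)
write.csv(df, file.path(out, "filtered_table.csv"), row.names = FALSE, na = "")
write.csv(filtered$features, file.path(out, "filtered_info.csv"),
          row.names = FALSE)
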