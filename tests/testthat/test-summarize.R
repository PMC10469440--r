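test_that("group summaries report median and IQR and drop small groups", {
  res <- data.frame(feature_id = sprintf("F%02d", 1:7),
                    icc = c(0.2, 0.4, 0.6, 0.5, 0.9, 0.3, 0.7))
  grp <- data.frame(feature_id = res$feature_id,
                    group = c("a", "a", "a", "b", "b", "b", "b"))
  out <- summarize_groups(res, grp, min_group_size = 4)
  expect_equal(out$group, "b")
  expect_equal(out$n, 4)
  excl <- attr(out, "excluded")
  expect_equal(excl$group, "a")
  expect_equal(excl$median_icc, 0.4)
  expect_equal(excl$iqr, 0.2)
  expect_error(summarize_groups(res[0, ], grp), "non-empty")
})

test_that("synthetic classes with distinct true ICCs are recovered in group medians", {
  # two classes of 9 features each, true ICCs 0.70 and 0.44
  des <- study_design(deterministic_repeats = TRUE)
  mk <- function(icc, seed) {
    spec <- feature_spec(n_features = 9, mu_range = c(12, 12),
                         sigma_within_sq = 1 - icc,
                         sigma_subject_sq = icc - 0.04,
                         sigma_center_sq = 0.04, detection_target = 1)
    simulate_study(des, spec, seed = seed)
  }
  sim_hi <- mk(0.70, 101)
  sim_lo <- mk(0.44, 102)
  m <- cbind(sim_hi$features$intensities,
             sim_lo$features$intensities)
  colnames(m) <- sprintf("F%02d", 1:18)
  tab <- feature_table(m)
  b <- run_feature_batch(tab, sim_hi$metadata,
                         mcmc = mcmc_settings(1500, 2), master_seed = 7,
                         estimands = "three_level")
  grp <- data.frame(feature_id = colnames(m),
                    group = rep(c("hi", "lo"), each = 9))
  out <- summarize_groups(b$results, grp)
  expect_lt(abs(out$median_icc[out$group == "hi"] - 0.70), 0.05)
  expect_lt(abs(out$median_icc[out$group == "lo"] - 0.44), 0.05)
})

test_that("centre-stratified fits are homogeneous under a homogeneous truth", {
  sim <- quick_sim(n_features = 3, centers = c(40, 40, 40),
                   s = c(0.5, 0.5, 0), seed = 103)
  strat <- stratify_by_center(sim$features, sim$metadata,
                              mcmc = mcmc_settings(1200, 2), master_seed = 8)
  med <- tapply(strat$icc, strat$center_id, median)
  expect_equal(length(med), 3)
  expect_lt(max(med) - min(med), 0.25)
})

test_that("a centre without replicated subjects is skipped with a warning", {
  sim <- quick_sim(n_features = 1, centers = c(20, 3), seed = 104)
  md <- sim$metadata
  # strip centre 2 down to singleton subjects
  c2 <- md$subject_id[md$center_id == "C2"]
  drop <- md$center_id == "C2" & md$session == 2
  md <- md[!drop, ]
  tab <- feature_table(
    sim$features$intensities[rownames(sim$features$intensities) %in%
                               md$sample_id, , drop = FALSE],
    sim$features$features)
  expect_warning(strat <- stratify_by_center(tab, md,
                                             mcmc = mcmc_settings(600, 2),
                                             master_seed = 9),
                 "skipped")
  expect_equal(unique(strat$center_id), "C1")
})

test_that("single-centre stratification equals a plain two-level run", {
  sim <- quick_sim(n_features = 2, centers = 30, seed = 105)
  strat <- suppressWarnings(
    stratify_by_center(sim$features, sim$metadata,
                       mcmc = mcmc_settings(800, 2), master_seed = 10))
  plain <- run_feature_batch(sim$features, sim$metadata,
                             spec = model_spec(levels = 2),
                             mcmc = mcmc_settings(800, 2),
                             master_seed = feature_seed(10, 1000003L))
  expect_equal(strat$icc, plain$results$icc)
})
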