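test_that("deterministic repeat assignment reproduces the four-centre cohort", {
  sim <- simulate_study(study_design(deterministic_repeats = TRUE),
                        feature_spec(n_features = 2), seed = 1)
  md <- sim$metadata
  expect_equal(length(unique(md$subject_id)), 157)
  expect_equal(nrow(md), 298)
  reps <- table(table(md$subject_id))
  expect_equal(unname(reps[["2"]]), 141)
  expect_equal(unname(reps[["1"]]), 16)
  expect_equal(sort(as.integer(table(md$center_id[!duplicated(md$subject_id)]))),
               sort(c(48L, 25L, 43L, 41L)))
  expect_true(all(c("sample_id", "subject_id", "center_id", "session",
                    "age", "sex", "bmi", "date") %in% names(md)))
})

test_that("random repeat assignment hits the expected sample count on average", {
  ns <- vapply(1:20, function(s) {
    nrow(simulate_study(study_design(), feature_spec(n_features = 1),
                        seed = s)$metadata)
  }, numeric(1))
  expect_gt(mean(ns), 290)
  expect_lt(mean(ns), 306)
})

test_that("zero within-subject variance gives identical replicate intensities", {
  sim <- quick_sim(s = c(0, 0.5, 0.1), detection = 1)
  m <- sim$features$intensities
  md <- sim$metadata
  for (sj in unique(md$subject_id)) {
    rows <- md$sample_id[md$subject_id == sj]
    if (length(rows) == 2) {
      expect_equal(m[rows[1], ], m[rows[2], ])
    }
  }
})

test_that("simulation is byte-identical under the same seed", {
  a <- simulate_study(study_design(), feature_spec(n_features = 3), seed = 42)
  b <- simulate_study(study_design(), feature_spec(n_features = 3), seed = 42)
  expect_identical(a, b)
  c <- simulate_study(study_design(), feature_spec(n_features = 3), seed = 43)
  expect_false(identical(a$features$intensities, c$features$intensities))
})

test_that("log-intensity moments match the three-level covariance structure", {
  # (1,1,1) truth: total variance 3; same-subject covariance 2 (corr 2/3);
  # same-centre cross-subject covariance 1. Many centres keep the empirical
  # centre variance close to its expectation.
  sim <- simulate_study(
    study_design(center_sizes = rep(20, 100), repeat_fraction = 1),
    feature_spec(n_features = 1, mu_range = c(12, 12), sigma_within_sq = 1,
                 sigma_subject_sq = 1, sigma_center_sq = 1,
                 detection_target = 1),
    seed = 5
  )
  y <- log(sim$features$intensities[, 1])
  md <- sim$metadata
  expect_lt(abs(var(y) / 3 - 1), 0.05)
  first <- y[md$session == 1][match(unique(md$subject_id),
                                    md$subject_id[md$session == 1])]
  second <- y[md$session == 2][match(unique(md$subject_id),
                                     md$subject_id[md$session == 2])]
  expect_lt(abs(cor(first, second) - 2 / 3), 0.05)
  # same-centre cross-subject covariance ~ sigma3_sq = 1
  subj_mean <- tapply(y, md$subject_id, mean)
  cent_of <- tapply(md$center_id, md$subject_id, function(x) x[1])
  cent_mean <- tapply(subj_mean, cent_of, mean)
  expect_lt(abs(var(cent_mean) - 1) / 3, 0.2)
})

test_that("ground-truth ICC is the exact arithmetic function of the variances", {
  sim <- simulate_study(study_design(), feature_spec(n_features = 10), seed = 2)
  tr <- sim$truth
  expect_equal(tr$icc, (tr$sigma2_sq + tr$sigma3_sq) /
                 (tr$sigma1_sq + tr$sigma2_sq + tr$sigma3_sq))
})

test_that("generator defaults are calibrated to the multicentre serum regime", {
  # across many features: mean between-centre share near 6% of total
  # variance, ICC distribution centred near 0.5
  sim <- simulate_study(study_design(), feature_spec(n_features = 400),
                        seed = 17)
  tr <- sim$truth
  share <- tr$sigma3_sq / (tr$sigma1_sq + tr$sigma2_sq + tr$sigma3_sq)
  expect_lt(abs(mean(share) - 0.06), 0.03)
  expect_gt(median(tr$icc), 0.4)
  expect_lt(median(tr$icc), 0.65)
  expect_true(all(tr$detection_target >= 0.4 & tr$detection_target <= 1))
})

test_that("covariate effects shift log-intensities as specified", {
  spec <- feature_spec(n_features = 1, mu_range = c(12, 12),
                       sigma_within_sq = 1e-8, sigma_subject_sq = 1e-8,
                       sigma_center_sq = 1e-8, detection_target = 1,
                       covariate_effects = list(sex = 1))
  sim <- simulate_study(study_design(deterministic_repeats = TRUE), spec,
                        seed = 3)
  y <- log(sim$features$intensities[, 1])
  md <- sim$metadata
  gap <- mean(y[md$sex == 1]) - mean(y[md$sex == 0])
  expect_lt(abs(gap - 1), 0.01)
})

test_that("degenerate designs and specs are rejected", {
  expect_error(study_design(center_sizes = integer(0)), "centre sizes")
  expect_error(study_design(center_sizes = c(5, 0)), "centre sizes")
  expect_error(study_design(repeat_fraction = 1.2), "repeat_fraction")
  expect_error(feature_spec(sigma_subject_sq = -1), "nonnegative")
  expect_error(feature_spec(detection_target = 0), "detection-rate")
  expect_error(feature_spec(detection_target = 1.1), "detection-rate")
  expect_error(simulate_study(study_design(), feature_spec()), "seed")
})

test_that("censoring at a target rate keeps exactly the target fraction", {
  set.seed(1)
  v <- exp(rnorm(100, 10))
  cz <- censor_at_rate(v, 0.6)
  expect_equal(sum(!is.na(cz$values)), 60)
  expect_gte(min(cz$values, na.rm = TRUE), cz$threshold)

  full <- censor_at_rate(v, 1.0)
  expect_equal(sum(is.na(full$values)), 0)
  expect_lt(full$threshold, min(v))

  expect_error(censor_at_rate(numeric(0), 0.5), "non-empty")
  expect_error(censor_at_rate(v, 0), "target_rate")
})
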