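fast_mcmc <- mcmc_settings(1500, 2, ess_threshold = 100)

test_that("uncensored posterior medians track a REML oracle", {
  sim <- quick_sim(centers = rep(30, 4), s = c(1, 1, 0.25), seed = 21)
  y <- log(sim$features$intensities[, 1])
  md <- sim$metadata
  fit <- fit_censored_model(y, min(y) - 1, md$subject_id, md$center_id,
                            mcmc = mcmc_settings(2000, 4), seed = 1)
  fm <- lme4::lmer(y ~ 1 + (1 | subject_id) + (1 | center_id), data = md,
                   REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fm))
  reml <- setNames(vc$vcov, vc$grp)
  med <- apply(fit$draws[, 1:3], 2, median)
  # within- and between-subject variances are well identified (120 subjects)
  expect_lt(abs(med["sigma1_sq"] - reml["Residual"]) / reml["Residual"], 0.10)
  expect_lt(abs(med["sigma2_sq"] - reml["subject_id"]) / reml["subject_id"], 0.15)
})

test_that("posterior matches an independent MCMC engine on the same priors", {
  suppressMessages(library(rjags))
  sim <- quick_sim(centers = rep(25, 4), s = c(1, 1, 0.25), seed = 31,
                   detection = 0.7)
  v <- sim$features$intensities[, 1]
  md <- sim$metadata
  lod <- log(min(v, na.rm = TRUE))
  y <- log(v)
  fit <- fit_censored_model(y, lod, md$subject_id, md$center_id,
                            mcmc = mcmc_settings(4000, 2), seed = 1)
  med <- apply(fit$draws[, 1:3], 2, median)

  A <- 2.5 * sd(y, na.rm = TRUE)
  model <- "model{
    for(i in 1:n){ y[i] ~ dnorm(a[s[i]], tau1); det[i] ~ dinterval(y[i], lim[i]) }
    for(j in 1:S){ a[j] ~ dnorm(m[c[j]], tau2) }
    for(k in 1:C){ m[k] ~ dnorm(b0, tau3) }
    b0 ~ dt(mu0, pow(A,-2), 3)
    sd1 ~ dt(0, pow(A,-2), 3) T(0,); tau1 <- pow(sd1,-2)
    sd2 ~ dt(0, pow(A,-2), 3) T(0,); tau2 <- pow(sd2,-2)
    sd3 ~ dt(0, pow(A,-2), 3) T(0,); tau3 <- pow(sd3,-2)
  }"
  s <- as.integer(factor(md$subject_id))
  cmap <- tapply(as.integer(factor(md$center_id)), s, function(x) x[1])
  jm <- jags.model(
    textConnection(model),
    data = list(y = y, det = as.integer(!is.na(y)),
                lim = rep(lod, length(y)), s = s, c = as.integer(cmap),
                n = length(y), S = max(s), C = 4, A = A,
                mu0 = median(y, na.rm = TRUE)),
    inits = list(y = ifelse(is.na(y), lod - 0.3, NA),
                 .RNG.name = "base::Mersenne-Twister", .RNG.seed = 1),
    n.chains = 1, quiet = TRUE
  )
  update(jm, 1500, progress.bar = "none")
  jm_draws <- coda.samples(jm, c("sd1", "sd2", "sd3"), 6000,
                           progress.bar = "none")
  jags_med <- apply(as.matrix(jm_draws)^2, 2, median)
  expect_lt(abs(med["sigma1_sq"] - jags_med["sd1"]) / jags_med["sd1"], 0.10)
  expect_lt(abs(med["sigma2_sq"] - jags_med["sd2"]) / jags_med["sd2"], 0.10)
  expect_lt(abs(med["sigma3_sq"] - jags_med["sd3"]) / jags_med["sd3"], 0.35)
})

test_that("revealing 20%-censored entries barely moves the variance medians", {
  sim <- quick_sim(centers = rep(50, 4), s = c(1, 1, 0.25), seed = 41)
  v <- sim$features$intensities[, 1]
  md <- sim$metadata
  cz <- censor_at_rate(v, 0.8)
  y_full <- log(v)
  y_cens <- log(cz$values)
  f_full <- fit_censored_model(y_full, min(y_full) - 50, md$subject_id,
                               md$center_id, mcmc = fast_mcmc, seed = 2)
  f_cens <- fit_censored_model(y_cens, log(cz$threshold), md$subject_id,
                               md$center_id, mcmc = fast_mcmc, seed = 2)
  for (p in c("sigma1_sq", "sigma2_sq")) {
    a <- median(f_full$draws[, p]); b <- median(f_cens$draws[, p])
    expect_lt(abs(a - b) / a, 0.15)
  }
})

test_that("two- and three-level fits agree when there is no centre variance", {
  sim <- quick_sim(centers = rep(40, 4), s = c(1, 1, 0), seed = 51)
  y <- log(sim$features$intensities[, 1])
  md <- sim$metadata
  f3 <- fit_censored_model(y, min(y) - 1, md$subject_id, md$center_id,
                           mcmc = fast_mcmc, seed = 3)
  f2 <- fit_censored_model(y, min(y) - 1, md$subject_id,
                           spec = model_spec(levels = 2),
                           mcmc = fast_mcmc, seed = 3)
  icc3 <- icc_three_level(f3)$icc
  tot2 <- f2$draws[, "sigma1_sq"] + f2$draws[, "sigma2_sq"]
  icc2 <- median(f2$draws[, "sigma2_sq"] / tot2)
  expect_lt(abs(icc3 - icc2), 0.06)
  expect_false("sigma3_sq" %in% colnames(f2$draws))
})

test_that("degenerate zero-spread data yields tiny variances and a flag", {
  n <- 40
  y <- rep(5, n)
  subj <- rep(1:20, each = 2)
  cent <- rep(1:2, each = 20)
  fit <- fit_censored_model(y, 0, subj, cent, mcmc = fast_mcmc, seed = 4)
  expect_true(fit$degenerate)
  expect_lt(median(fit$draws[, "sigma1_sq"]), 1e-4)
  expect_lt(median(fit$draws[, "sigma2_sq"]), 1e-4)
})

test_that("contract violations are rejected up front", {
  y <- rnorm(10)
  expect_error(fit_censored_model(rep(NA_real_, 10), 0, rep(1:5, 2),
                                  rep(1:2, 5)),
               "all observations are censored")
  expect_error(fit_censored_model(y, 0, 1:10, rep(1:2, 5)),
               "replicate")
  # subject 1 appears in two centres: not nested
  expect_error(fit_censored_model(y, 0, c(1, 1, 2:9), c(1, 2, rep(1, 8))),
               "nested")
  expect_error(fit_censored_model(y, 0, rep(1:5, 2), rep(1, 10)),
               ">= 2 centres")
  # finite lod only required for censored entries
  expect_no_error(fit_censored_model(y, Inf, rep(1:5, each = 2),
                                     rep(1:2, c(4, 6)),
                                     mcmc = mcmc_settings(100, 2)))
})

test_that("sampling is reproducible and draw counts follow the settings", {
  sim <- quick_sim(seed = 61)
  y <- log(sim$features$intensities[, 1])
  md <- sim$metadata
  mc <- mcmc_settings(600, 3, burn_in = 200, thin = 2)
  f1 <- fit_censored_model(y, min(y) - 1, md$subject_id, md$center_id,
                           mcmc = mc, seed = 9)
  f2 <- fit_censored_model(y, min(y) - 1, md$subject_id, md$center_id,
                           mcmc = mc, seed = 9)
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$draws), 3 * (600 - 200) / 2)
  expect_true(all(f1$draws[, 1:3] >= 0))
})

test_that("age smooth basis is centred and df=1 is a linear term", {
  age <- c(40, 45, 50, 55, 60, 65, 70, 75)
  b1 <- build_age_smooth(age, df = 1)
  expect_equal(ncol(b1), 1)
  expect_equal(cor(b1[, 1], age), 1)
  expect_lt(abs(mean(b1[, 1])), 1e-12)
  b3 <- build_age_smooth(age, df = 3)
  expect_equal(ncol(b3), 3)
  expect_true(all(abs(colMeans(b3)) < 1e-12))
  expect_error(build_age_smooth(rep(50, 5)), "constant")
  expect_error(build_age_smooth(c(1, 2), df = 3), "distinct ages")
})

test_that("the spline basis reproduces a natural cubic spline exactly", {
  x <- seq(40, 80, length.out = 60)
  # build the target as a natural cubic spline whose knots coincide with
  # those of the df=5 basis, so it must lie exactly in the basis span
  B <- splines::ns(x, df = 5)
  kx <- c(attr(B, "Boundary.knots")[1], attr(B, "knots"),
          attr(B, "Boundary.knots")[2])
  target <- spline(kx, c(0.2, 1.1, 0.4, 0.9, 0.7, 1.3), method = "natural",
                   xout = x)$y
  fit <- lm(target ~ B)
  expect_lt(max(abs(fitted(fit) - target)), 1e-6)
  # centred variant spans the same space up to the intercept
  Bc <- build_age_smooth(x, df = 5)
  fitc <- lm(target ~ Bc)
  expect_lt(max(abs(fitted(fitc) - target)), 1e-6)
})

test_that("batch fitting isolates failures and derives per-feature seeds", {
  sim <- quick_sim(n_features = 5, seed = 71, detection = 0.9)
  m <- sim$features$intensities
  m[, 3] <- NA # feature with no detected value
  tab <- feature_table(m, sim$features$features)
  b <- run_feature_batch(tab, sim$metadata, mcmc = fast_mcmc, master_seed = 6)
  main <- b$results[b$results$estimand == "three_level" |
                      b$results$status != "ok", ]
  expect_equal(nrow(main), 5)
  expect_match(main$status[main$feature_id == "F0003"], "failed")
  expect_equal(sum(main$status == "ok"), 4)

  # a single-feature refit with the derived seed reproduces the batch row
  f4 <- sim$features$intensities[, 4]
  y <- log(f4)
  solo <- fit_censored_model(y, log(min(f4, na.rm = TRUE)),
                             sim$metadata$subject_id, sim$metadata$center_id,
                             mcmc = fast_mcmc, seed = feature_seed(6, 4))
  expect_equal(icc_three_level(solo, id = "F0004")$icc,
               main$icc[main$feature_id == "F0004"])

  b2 <- run_feature_batch(tab, sim$metadata, mcmc = fast_mcmc, master_seed = 6)
  expect_identical(b$results, b2$results)
})

test_that("batch rejects metadata that does not cover the samples", {
  sim <- quick_sim(n_features = 2, seed = 81)
  md <- sim$metadata[-1, ]
  expect_error(run_feature_batch(sim$features, md), "cover")
})

test_that("recovery batches converge for nearly all features at default settings", {
  rec <- run_recovery_suite(n_features = 50, mcmc = mcmc_settings(),
                            master_seed = 3)
  expect_gte(mean(rec$per_feature$converged), 0.95)
})

test_that("split R-hat and ESS behave on iid and on drifting chains", {
  set.seed(14)
  iid <- matrix(rnorm(4000), 1000, 4)
  expect_lt(split_rhat(iid), 1.01)
  expect_gt(ess_bulk(iid), 2000)
  drift <- iid + outer(seq(0, 3, length.out = 1000), rep(1, 4))
  expect_gt(split_rhat(drift), 1.05)
})
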