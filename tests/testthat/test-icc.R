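test_that("ICC estimands are exact on constant draws", {
  expect_equal(icc_three_level(const_draws(1, 1, 1))$icc, 2 / 3)
  expect_equal(icc_three_level(const_draws(1, 0, 0))$icc, 0)
  expect_equal(icc_three_level(const_draws(0, 1, 1))$icc, 1)
  expect_equal(icc_within_center(const_draws(1, 1, 1))$icc, 1 / 3)
})

test_that("ICC is the median of per-draw ratios, not the ratio of medians", {
  d <- rbind(c(1, 1, 0), c(1, 3, 0))
  colnames(d) <- c("sigma1_sq", "sigma2_sq", "sigma3_sq")
  r <- icc_three_level(d)
  expect_equal(r$icc, median(c(0.5, 0.75))) # 0.625
  expect_false(isTRUE(all.equal(r$icc, 2 / 3))) # ratio of medians
})

test_that("within-centre ICC never exceeds the three-level ICC draw-wise", {
  set.seed(11)
  d <- cbind(sigma1_sq = rexp(500), sigma2_sq = rexp(500),
             sigma3_sq = rexp(500))
  tot <- rowSums(d)
  expect_true(all(d[, "sigma2_sq"] / tot <=
                    (d[, "sigma2_sq"] + d[, "sigma3_sq"]) / tot))
  expect_lte(icc_within_center(d)$icc, icc_three_level(d)$icc)
  # with no centre variance the two estimands coincide
  d0 <- const_draws(1.3, 0.6, 0)
  expect_equal(icc_within_center(d0)$icc, icc_three_level(d0)$icc)
})

test_that("ICC is monotone in each variance component", {
  base <- c(1, 1, 0.5)
  f <- function(s) (s[2] + s[3]) / sum(s)
  for (eps in c(0.1, 0.5)) {
    expect_gt(f(base + c(0, eps, 0)), f(base))
    expect_gt(f(base + c(0, 0, eps)), f(base))
    expect_lt(f(base + c(eps, 0, 0)), f(base))
  }
})

test_that("variance proportions are exact on constant draws and near-sum to one", {
  p <- variance_proportions(const_draws(2, 1, 1))
  expect_equal(unname(p), c(0.50, 0.25, 0.25))
  # per-draw proportions sum to one exactly; their marginal medians to a
  # few percent for posterior-like skews (inverse-gamma with the effective
  # degrees of freedom of a typical fit: ~300 obs, ~150 subjects, 4 centres)
  set.seed(12)
  d <- cbind(sigma1_sq = 150 / rgamma(500, 150),
             sigma2_sq = 75 / rgamma(500, 75),
             sigma3_sq = 0.1 * 2 / rgamma(500, 2))
  expect_lt(abs(sum(variance_proportions(d)) - 1), 0.05)
})

test_that("negative variance draws are rejected", {
  d <- const_draws(1, 1, 1)
  d[3, "sigma2_sq"] <- -0.1
  expect_error(icc_three_level(d), "negative variance")
})

test_that("data-scale ICC matches the lognormal closed form and its limits", {
  expect_equal(icc_two_level_datascale(0, sigma_w_sq = 2), 0)
  expect_equal(icc_two_level_datascale(1, sigma_w_sq = 1),
               (exp(1) - 1) / (exp(2) - 1))
  # shrinking variances at fixed ratio converge to the log-scale ICC
  r <- 0.7
  small <- icc_two_level_datascale(r * 1e-4, sigma_w_sq = (1 - r) * 1e-4)
  expect_lt(abs(small - r), 1e-4)
})

test_that("data-scale ICC never exceeds the log-scale ICC on a grid", {
  grid <- expand.grid(b = c(0.1, 0.5, 1, 2), w = c(0.1, 0.5, 1, 2))
  ds <- icc_two_level_datascale(grid$b, sigma_w_sq = grid$w)
  ls <- grid$b / (grid$b + grid$w)
  expect_true(all(ds <= ls))
  expect_true(all(ds >= 0 & ds <= 1))
})

test_that("data-scale ICC refuses three-level draws", {
  expect_error(icc_two_level_datascale(const_draws(1, 1, 0.2)),
               "two-level")
})

test_that("repeatability classes follow the conventional boundaries", {
  expect_equal(classify_repeatability(c(0.39, 0.40, 0.75, 0.751, 0.64)),
               c("poor", "fair", "fair", "excellent", "fair"))
  expect_equal(classify_repeatability(c(0, 1)), c("poor", "excellent"))
  expect_error(classify_repeatability(1.2), "0, 1")
})

test_that("median-of-draws ICC equals the closed form when draws are constant", {
  d <- const_draws(0.8, 1.2, 0.3, n = 50)
  expect_equal(icc_three_level(d)$icc, 1.5 / 2.3)
  expect_equal(icc_three_level(d)$lower, icc_three_level(d)$upper)
})
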