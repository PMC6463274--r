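test_that("config validation and presets", {
  expect_error(dp_config(n_iter = 100, burn_in = 200), "n_iter")
  expect_error(dp_config(a0 = 4), "both a0 and b0")
  expect_error(dp_config(alpha = -1), "positive")
  cfg1 <- dp_config(preset = "dp1")
  expect_equal(c(cfg1$a0, cfg1$b0), c(4, 4))
  cfg2 <- dp_config(preset = "dp2")
  expect_equal(c(cfg2$a0, cfg2$b0), c(10, 0.10))
  cfg3 <- dp_config(preset = "dp3")
  expect_false(cfg3$hyper)
  expect_equal(cfg3$alpha, 20)
})

test_that("degenerate and limiting partition behavior", {
  cfg <- dp_config(alpha = 1, n_iter = 200, burn_in = 50, thin = 1)
  one <- dp_fit(provider_counts("A", 5, 10), cfg, seed = 1)
  expect_true(all(one$cluster_counts == 1))

  # alpha -> 0: everyone in one cluster essentially always
  cfg0 <- dp_config(alpha = 1e-6, n_iter = 600, burn_in = 100, thin = 1)
  pc <- provider_counts(1:4, y = c(2, 5, 9, 12), n = rep(20, 4))
  f0 <- dp_fit(pc, cfg0, seed = 2)
  expect_gte(mean(f0$cluster_counts == 1), 0.999)
})

test_that("two-provider posterior matches exact partition enumeration", {
  y <- c(2, 18)
  n <- c(20, 20)
  pc <- provider_counts(1:2, y = y, n = n)
  cfg <- dp_config(alpha = 1, n_iter = 21000, burn_in = 1000, thin = 4)
  fit <- dp_fit(pc, cfg, seed = 5)
  p_same_hat <- mean(fit$cluster_counts == 1)
  p_same <- dp2_prob_same(y, n, alpha = 1)
  R <- length(fit$cluster_counts)
  mc_se <- sqrt(max(p_same * (1 - p_same), 1e-12) / R)
  expect_lt(abs(p_same_hat - p_same), 3 * mc_se + 1e-4)
})

test_that("three-provider cluster counts match the 5-partition enumeration", {
  y <- c(3, 5, 15)
  n <- c(20, 20, 20)
  pc <- provider_counts(1:3, y = y, n = n)
  cfg <- dp_config(alpha = 1, n_iter = 21000, burn_in = 1000, thin = 4)
  fit <- dp_fit(pc, cfg, seed = 6)
  probs <- dp3_cluster_count_probs(y, n, alpha = 1)
  R <- length(fit$cluster_counts)
  for (k in 1:3) {
    phat <- mean(fit$cluster_counts == k)
    mc_se <- sqrt(max(probs[k] * (1 - probs[k]), 1e-12) / R)
    expect_lt(abs(phat - probs[k]), 3 * mc_se + 1e-3)
  }
})

test_that("sampling is reproducible given seed and config", {
  pc <- provider_counts(1:5, y = c(1, 4, 7, 9, 12), n = rep(15, 5))
  cfg <- dp_config(preset = "dp1", n_iter = 300, burn_in = 100, thin = 2)
  f1 <- dp_fit(pc, cfg, seed = 11)
  f2 <- dp_fit(pc, cfg, seed = 11)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$alphas, f2$alphas)
})

test_that("Rao-Blackwellized density matches the single-provider closed form", {
  pc <- provider_counts("A", 5, 10)
  for (alpha in c(0.5, 2)) {
    cfg <- dp_config(alpha = alpha, n_iter = 60, burn_in = 10, thin = 1)
    fit <- dp_fit(pc, cfg, seed = 3)
    d <- dp_density(fit, pc)
    w <- alpha / (alpha + 1)
    u <- c(0.1, 0.3, 0.5, 0.8)
    expect_equal(d$pdf_fun(u),
                 w * dbeta(u, 1, 1) + (1 - w) * dbeta(u, 6, 6),
                 tolerance = 1e-12)
  }
  # unit mass and bounded variance
  d <- dp_density(dp_fit(pc, dp_config(alpha = 1, n_iter = 60, burn_in = 10,
                                       thin = 1), seed = 3), pc)
  expect_equal(integrate(d$pdf_fun, 0, 1, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
  expect_lte(d$variance, 0.25)
})

test_that("prior cluster distribution matches the analytic CRP mean", {
  cfg <- dp_config(alpha = 5)
  pr <- prior_cluster_distribution(100, cfg, n_draws = 20000, seed = 8)
  analytic <- sum(5 / (5 + 0:99))
  mc_se <- sd(pr$counts) / sqrt(20000)
  expect_lt(abs(mean(pr$counts) - analytic), 3 * mc_se)
  # alpha -> 0 limit: a single cluster
  pr0 <- prior_cluster_distribution(50, dp_config(alpha = 1e-9),
                                    n_draws = 1000, seed = 9)
  expect_true(all(pr0$counts == 1))
  expect_equal(sum(pr$table$probability), 1, tolerance = 1e-12)
})

test_that("the sampler run prior-only recovers the prior cluster-count law", {
  cfg <- dp_config(preset = "dp1", n_iter = 4000, burn_in = 500, thin = 2)
  pc <- provider_counts(1:30, y = rep(5, 30), n = rep(20, 30))
  fit <- dp_fit(pc, cfg, seed = 21, prior_only = TRUE)
  pr <- prior_cluster_distribution(30, cfg, n_draws = 20000, seed = 22)
  R <- length(fit$cluster_counts)
  se <- sqrt(sd(pr$counts)^2 / R + sd(pr$counts)^2 / 20000)
  # Gibbs draws are autocorrelated; allow a dependence inflation factor
  expect_lt(abs(mean(fit$cluster_counts) - mean(pr$counts)), 5 * se)
})
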