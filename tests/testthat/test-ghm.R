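test_that("homogeneous cohorts give beta0 = logit(p) and sigma_b ~ 0", {
  pc <- provider_counts(1:20, y = rep(50, 20), n = rep(200, 20))
  fit <- fit_ghm(pc)
  expect_equal(fit$beta0, qlogis(0.25), tolerance = 0.02)
  expect_lt(fit$sigma_b, 0.05)
})

test_that("adaptive quadrature matches brute-force trapezoid integration", {
  spec <- scenario_spec("normal", sigma_b2 = 0.7^2, beta0 = -1.1, N = 500,
                        size_profile = "registry", seed = 42)
  pc <- simulate_cohort(spec)
  ours <- ghm_marginal_loglik(pc, beta0 = -1.1, sigma_b = 0.7)
  oracle <- trapezoid_marginal_loglik(pc, beta0 = -1.1, sigma_b = 0.7)
  expect_equal(ours, oracle, tolerance = 1e-6)
})

test_that("the fitted variance component recovers the truth on average", {
  B <- 200
  est <- vapply(seq_len(B), function(b) {
    spec <- scenario_spec("normal", sigma_b2 = 0.5, N = 300,
                          size_profile = "fixed30", seed = 5000L + b)
    fit_ghm(simulate_cohort(spec))$sigma_b^2
  }, numeric(1))
  mc_se <- sd(est) / sqrt(B)
  expect_lt(abs(mean(est) - 0.5), 3 * mc_se)
})

test_that("fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  pc <- toy_cohort(seed = 9, N = 120, n = 40)
  fit <- fit_ghm(pc)
  g <- lme4::glmer(cbind(y, n - y) ~ 1 + (1 | provider_id),
                   data = as.data.frame(pc), family = binomial, nAGQ = 25)
  expect_equal(fit$beta0, unname(lme4::fixef(g)), tolerance = 1e-3)
  expect_equal(fit$sigma_b,
               sqrt(unname(lme4::VarCorr(g)$provider_id[1])),
               tolerance = 5e-3)
})

test_that("logit-normal density and cdf have the closed-form values", {
  fit <- structure(list(beta0 = 0, sigma_b = 1, loglik = 0, n_quad = 25,
                        converged = TRUE), class = "ghm_fit")
  d <- ghm_density(fit)
  expect_equal(d$pdf_fun(0.5), 1 / (sqrt(2 * pi) * 0.25),
               tolerance = 1e-10)
  expect_equal(d$cdf(plogis(fit$beta0)), 0.5)
  # unit mass by adaptive quadrature of the closed form
  mass <- integrate(d$pdf_fun, 0, 1, rel.tol = 1e-10)$value
  expect_equal(mass, 1, tolerance = 1e-6)

  # degenerate fit flagged
  fit0 <- structure(list(beta0 = -1, sigma_b = 0, loglik = 0, n_quad = 25,
                         converged = TRUE), class = "ghm_fit")
  d0 <- ghm_density(fit0)
  expect_true(isTRUE(d0$degenerate))
  expect_equal(d0$variance, 0)
})

test_that("ghm_variance matches Monte Carlo and respects the p(1-p) bound", {
  fit <- structure(list(beta0 = 0, sigma_b = 1, loglik = 0, n_quad = 25,
                        converged = TRUE), class = "ghm_fit")
  v <- ghm_variance(fit)
  set.seed(1)
  draws <- plogis(rnorm(1e7))
  mc_var <- mean(draws^2) - mean(draws)^2
  mc_se <- sd((draws - mean(draws))^2) / sqrt(1e7)
  expect_lt(abs(v - mc_var), 3 * mc_se)
  m <- providervar:::ghm_moments(fit)[["mean"]]
  expect_lt(v, m * (1 - m))

  fit0 <- structure(list(beta0 = 0.3, sigma_b = 0, loglik = 0, n_quad = 25,
                         converged = TRUE), class = "ghm_fit")
  expect_equal(ghm_variance(fit0), 0)
})

test_that("analytic density matches a large-sample simulated KDE", {
  fit <- structure(list(beta0 = qlogis(0.25), sigma_b = sqrt(0.5),
                        loglik = 0, n_quad = 25, converged = TRUE),
                   class = "ghm_fit")
  d <- ghm_density(fit)
  set.seed(2)
  sim <- plogis(fit$beta0 + fit$sigma_b * rnorm(1e6))
  k <- kde(sim)
  grid <- seq(0.001, 0.999, length.out = 2001)
  diff2 <- (d$pdf_fun(grid) -
            approx(k$grid, k$pdf, xout = grid, yleft = 0,
                   yright = 0)$y)^2
  ed <- providervar:::simpson(diff2, grid[2] - grid[1])
  expect_lt(ed, 1e-3)
})

test_that("EB predictions shrink toward the center and match a fine-grid oracle", {
  fit <- structure(list(beta0 = -1, sigma_b = 0.6, loglik = 0, n_quad = 25,
                        converged = TRUE), class = "ghm_fit")
  # single-provider fine-grid numerical posterior oracle
  y <- 7; n <- 20
  b <- seq(-8, 8, length.out = 200001)
  w <- dbinom(y, n, plogis(fit$beta0 + b)) * dnorm(b, 0, fit$sigma_b)
  oracle <- sum(plogis(fit$beta0 + b) * w) / sum(w)
  ours <- providervar:::eb_posterior_means(fit, y, n)
  expect_equal(ours, oracle, tolerance = 1e-6)

  # full shrinkage when sigma_b ~ 0
  fit0 <- structure(list(beta0 = -1, sigma_b = 0, loglik = 0, n_quad = 25,
                         converged = TRUE), class = "ghm_fit")
  pc <- provider_counts(1:3, y = c(2, 5, 9), n = c(20, 20, 20))
  eb0 <- eb_predictions(fit0, pc)
  expect_true(all(abs(eb0$support_points - plogis(-1)) < 1e-10))

  # shrinkage direction on simulated data
  pc2 <- toy_cohort(seed = 31, N = 150, n = 20, sigma_b2 = 0.3)
  fit2 <- fit_ghm(pc2)
  eb2 <- eb_predictions(fit2, pc2)
  expect_lt(population_variance(eb2$support_points),
            population_variance(raw_proportions(pc2)))

  # posterior mode variant is also available and also shrinks
  ebm <- eb_predictions(fit2, pc2, type = "mode")
  expect_lt(population_variance(ebm$support_points),
            population_variance(raw_proportions(pc2)))
})
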