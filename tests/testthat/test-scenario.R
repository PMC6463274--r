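test_that("spec validation and seed determinism", {
  expect_error(scenario_spec("normal", sigma_b2 = 0), "sigma_b2")
  expect_error(scenario_spec("normal", N = 1), "N must be")
  expect_error(scenario_spec("normal", N = 5, size_profile = c(10, 20)),
               "explicit size_profile")
  spec <- scenario_spec("bimodal", sigma_b2 = 0.5, N = 40,
                        size_profile = "trial", seed = 3)
  expect_identical(gen_provider_probs(spec), gen_provider_probs(spec))
  expect_identical(gen_cluster_sizes(spec), gen_cluster_sizes(spec))
  expect_identical(as.data.frame(simulate_cohort(spec)),
                   as.data.frame(simulate_cohort(spec)))
})

test_that("random-effect laws have the standardized logit-scale moments", {
  n <- 1e6
  for (law in c("normal", "chisq", "bimodal")) {
    spec <- scenario_spec(law, sigma_b2 = 0.5, N = 10, seed = 99)
    set.seed(99)
    b <- providervar:::draw_b(spec, n)
    expect_lt(abs(mean(b)), 3 * sd(b) / sqrt(n))
    v <- mean((b - mean(b))^2)
    se_v <- sd((b - mean(b))^2) / sqrt(n)
    expect_lt(abs(v - 0.5), 3 * se_v)
    if (law == "chisq") {
      sk <- mean(((b - mean(b)) / sd(b))^3)
      expect_equal(sk, 2 * sqrt(2), tolerance = 0.05)
    }
    if (law == "bimodal") {
      # two clear modes at +/- delta on the logit scale
      p <- providervar:::bimodal_pars(0.5)
      dens <- density(b)
      at <- function(x) dens$y[which.min(abs(dens$x - x))]
      expect_gt(at(-p[["delta"]]), at(0))
      expect_gt(at(p[["delta"]]), at(0))
    }
  }
})

test_that("degenerate variance collapses probabilities to expit(beta0)", {
  spec <- scenario_spec("normal", sigma_b2 = 1e-12, N = 100, seed = 1)
  p <- gen_provider_probs(spec)
  expect_true(all(abs(p - plogis(spec$beta0)) < 1e-4))
})

test_that("site-size profiles hit the printed medians and IQRs", {
  for (prof in list(list(name = "trial", med = c(23, 27), q = c(17, 43)),
                    list(name = "registry", med = c(60, 70),
                         q = c(38, 126)))) {
    spec <- scenario_spec("normal", sigma_b2 = 0.05, N = 1e5,
                          size_profile = prof$name, seed = 12)
    n <- gen_cluster_sizes(spec)
    expect_gte(median(n), prof$med[1])
    expect_lte(median(n), prof$med[2])
    qs <- quantile(n, c(0.25, 0.75))
    expect_lt(abs(qs[1] - prof$q[1]) / prof$q[1], 0.15)
    expect_lt(abs(qs[2] - prof$q[2]) / prof$q[2], 0.15)
    expect_true(all(n >= 10))
  }
  spec <- scenario_spec("normal", N = 300, size_profile = "fixed20",
                        seed = 1)
  expect_true(all(gen_cluster_sizes(spec) == 20))
})

test_that("binomial outcome generation is correct at the boundaries", {
  expect_equal(gen_outcomes(c(1, 1), c(10, 20), seed = 1)$y, c(10L, 20L))
  expect_equal(gen_outcomes(c(0, 0), c(10, 20), seed = 1)$y, c(0L, 0L))
  big <- gen_outcomes(0.5, 1e6, seed = 2)
  expect_lt(abs(big$y / big$n - 0.5), 3 * sqrt(0.25 / 1e6))
})

test_that("exact density, cdf and variance accessors are consistent", {
  for (law in c("normal", "chisq", "bimodal")) {
    spec <- scenario_spec(law, sigma_b2 = 0.05, N = 10, seed = 1)
    # unit mass; split at the chi-square law's (integrable) density spike
    split <- if (law == "chisq") {
      plogis(spec$beta0 - sqrt(0.05) / sqrt(2))
    } else {
      0.5
    }
    piece <- function(lo, hi) {
      integrate(function(u) true_density(spec, u), lo, hi,
                rel.tol = 1e-8, subdivisions = 2000,
                stop.on.error = FALSE)$value
    }
    mass <- piece(1e-10, split) + piece(split, 1 - 1e-10)
    expect_equal(mass, 1, tolerance = 1e-5)
    # cdf consistency with the density
    x0 <- 0.3
    F0 <- piece(1e-10, min(split, x0)) +
      if (split < x0) piece(split, x0) else 0
    expect_equal(true_cdf(spec, x0), F0, tolerance = 1e-5)
    # variance against a large Monte Carlo draw
    set.seed(31)
    p <- plogis(spec$beta0 + providervar:::draw_b(spec, 1e7))
    mc_var <- mean((p - mean(p))^2)
    se <- sd((p - mean(p))^2) / sqrt(1e7)
    expect_lt(abs(true_variance(spec) - mc_var), 3 * se)
  }
  # symmetry of the normal law on the logit scale
  spec <- scenario_spec("normal", sigma_b2 = 0.5, N = 10, seed = 1)
  expect_equal(true_cdf(spec, plogis(spec$beta0)), 0.5)
  expect_error(true_density(spec, c(0.5, 1.2)), "in \\(0,1\\)")
})

test_that("chisq law respects its one-sided support bound", {
  spec <- scenario_spec("chisq", sigma_b2 = 0.5, N = 10, seed = 1)
  sb <- sqrt(0.5)
  b_min <- -sb / sqrt(2)
  below <- plogis(spec$beta0 + b_min - 0.05)
  expect_equal(true_density(spec, below), 0)
  expect_equal(true_cdf(spec, below), 0)
})

test_that("cohort export round-trips counts and truth", {
  spec <- scenario_spec("normal", sigma_b2 = 0.5, N = 25,
                        size_profile = "fixed20", seed = 7)
  fc <- tempfile(fileext = ".csv")
  ft <- tempfile(fileext = ".json")
  pc <- export_cohort(spec, fc, ft)
  rt <- read_counts(fc)
  expect_equal(rt$provider_id, pc$provider_id)
  expect_equal(rt$y, pc$y)
  expect_equal(rt$n, pc$n)
  truth <- jsonlite::read_json(ft)
  expect_equal(truth$law, "normal")
  expect_equal(truth$true_variance, true_variance(spec), tolerance = 1e-12)
})
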