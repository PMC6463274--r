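# Independent oracles used across tests. These deliberately avoid the
# package's own numerical paths: brute-force quadrature, direct EM,
# partition enumeration.

# Marginal log-likelihood of the random-intercept logistic model by
# brute-force trapezoid integration over the random effect.
trapezoid_marginal_loglik <- function(counts, beta0, sigma_b,
                                      n_points = 10000, width = 10) {
  b <- seq(-width * sigma_b, width * sigma_b, length.out = n_points)
  h <- b[2] - b[1]
  sum(vapply(seq_len(nrow(counts)), function(i) {
    f <- dbinom(counts$y[i], counts$n[i], plogis(beta0 + b)) *
      dnorm(b, 0, sigma_b)
    log(h * (sum(f) - (f[1] + f[n_points]) / 2))
  }, numeric(1)))
}

# Direct nonparametric-MLE EM on a fixed grid, run to (near) convergence.
npml_em <- function(y, n, grid, n_iter) {
  L <- t(vapply(seq_along(y),
                function(i) dbinom(y[i], n[i], grid),
                numeric(length(grid))))
  f <- rep(1 / length(grid), length(grid))
  for (v in seq_len(n_iter)) {
    A <- sweep(L, 2, f, `*`)
    post <- A / rowSums(A)
    f <- colMeans(post)
  }
  f
}

# Exact posterior over the 2 partitions of two providers under the DP
# beta-binomial model with fixed alpha and Beta(a1, b1) base.
lbb <- function(y, n, a, b) lchoose(n, y) + lbeta(a + y, b + n - y) - lbeta(a, b)

dp2_prob_same <- function(y, n, alpha, a1 = 1, b1 = 1) {
  l_together <- lbb(y[1], n[1], a1, b1) +
    lbb(y[2], n[2], a1 + y[1], b1 + n[1] - y[1])
  l_apart <- lbb(y[1], n[1], a1, b1) + lbb(y[2], n[2], a1, b1)
  # CRP prior: P(together) = 1/(1+alpha), P(apart) = alpha/(1+alpha)
  w_together <- log(1 / (1 + alpha)) + l_together
  w_apart <- log(alpha / (1 + alpha)) + l_apart
  1 / (1 + exp(w_apart - w_together))
}

# Exact posterior over the 5 partitions of three providers (fixed alpha).
dp3_cluster_count_probs <- function(y, n, alpha, a1 = 1, b1 = 1) {
  parts <- list(list(1:3), list(1:2, 3), list(c(1, 3), 2), list(2:3, 1),
                list(1, 2, 3))
  # CRP partition probability: alpha^K prod (|c|-1)! / prod_{i=0}^{N-1} (alpha+i)
  crp_log <- function(p) {
    sizes <- lengths(p)
    length(p) * log(alpha) + sum(lgamma(sizes)) -
      sum(log(alpha + 0:2))
  }
  marg_log <- function(idx) {
    a <- a1
    b <- b1
    ll <- 0
    for (i in idx) {
      ll <- ll + lbb(y[i], n[i], a, b)
      a <- a + y[i]
      b <- b + n[i] - y[i]
    }
    ll
  }
  lw <- vapply(parts, function(p) {
    crp_log(p) + sum(vapply(p, marg_log, numeric(1)))
  }, numeric(1))
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  k <- vapply(parts, length, integer(1))
  vapply(1:3, function(kk) sum(w[k == kk]), numeric(1))
}

# quick cohort for tests
toy_cohort <- function(seed = 1, N = 60, n = 30, law = "normal",
                       sigma_b2 = 0.5) {
  simulate_cohort(scenario_spec(law, sigma_b2 = sigma_b2, N = N,
                                size_profile = rep(n, N), seed = seed))
}
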