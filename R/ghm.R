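## Gaussian hierarchical model: random-intercept logistic regression
##   Y_i | p_i ~ Binomial(n_i, p_i),  logit(p_i) = beta0 + b_i,
##   b_i ~ Normal(0, sigma_b^2),
## fitted by maximizing the marginal likelihood with the random effect
## integrated out by adaptive (mode-centered, curvature-scaled)
## Gauss-Hermite quadrature.

# log(1 + exp(x)) without overflow
log1pexp <- function(x) ifelse(x > 33, x, log1p(exp(x)))

# Per-provider marginal log-likelihood contributions, adaptive GH.
# y, n vectors (one entry per provider or per unique (y,n) group).
ghm_loglik_terms <- function(beta0, sigma_b, y, n, n_quad = 25) {
  if (sigma_b < 1e-8) {
    return(stats::dbinom(y, n, expit(beta0), log = TRUE))
  }
  # Newton for the conditional mode of
  #   l(b) = y(beta0+b) - n log(1+e^(beta0+b)) - b^2/(2 sigma^2)
  b <- rep(0, length(y))
  for (it in 1:30) {
    p <- expit(beta0 + b)
    g <- y - n * p - b / sigma_b^2
    h <- -n * p * (1 - p) - 1 / sigma_b^2
    step <- g / h
    b <- b - step
    if (max(abs(step)) < 1e-12) break
  }
  p <- expit(beta0 + b)
  s <- 1 / sqrt(n * p * (1 - p) + 1 / sigma_b^2)
  r <- gh_rule(n_quad)
  # nodes: b_k = mode + sqrt(2) s x_k; integral = sqrt(2) s sum w_k e^{x_k^2} g(b_k)
  bk <- outer(b, rep(1, n_quad)) + sqrt(2) * outer(s, r$x)
  eta <- beta0 + bk
  logint <- y * eta - n * log1pexp(eta) + lchoose(n, y) +
    stats::dnorm(bk, 0, sigma_b, log = TRUE)
  lw <- matrix(log(r$w) + r$x^2, nrow = length(y), ncol = n_quad,
               byrow = TRUE)
  log(sqrt(2) * s) + apply(logint + lw, 1, logsumexp)
}

#' Marginal log-likelihood of the Gaussian hierarchical model
#'
#' The binomial likelihood with the provider random intercept integrated out
#' by adaptive Gauss-Hermite quadrature centered at each provider's
#' conditional mode. Exposed so the quadrature can be checked against
#' independent integration.
#'
#' @param counts a [provider_counts] object.
#' @param beta0 intercept on the logit scale.
#' @param sigma_b random-effect standard deviation (>= 0).
#' @param n_quad number of quadrature nodes.
#' @return Scalar log-likelihood (binomial constants included).
#' @export
ghm_marginal_loglik <- function(counts, beta0, sigma_b, n_quad = 25) {
  stopifnot(inherits(counts, "provider_counts"))
  key <- paste(counts$y, counts$n)
  u <- !duplicated(key)
  terms <- ghm_loglik_terms(beta0, sigma_b, counts$y[u], counts$n[u], n_quad)
  sum(terms[match(key, key[u])])
}

#' Fit the Gaussian hierarchical model
#'
#' Maximizes the marginal likelihood over `(beta0, log sigma_b)` by
#' Nelder-Mead from a method-of-moments start, with one jittered restart on
#' failure. A boundary estimate `sigma_b ~ 0` is a valid result (no
#' heterogeneity), not an error.
#'
#' @param counts a [provider_counts] object with at least 2 providers.
#' @param n_quad number of adaptive Gauss-Hermite nodes.
#' @return An object of class `ghm_fit`: list with `beta0`, `sigma_b`,
#'   `loglik`, `n_quad`, `converged`.
#' @examples
#' spec <- scenario_spec("normal", sigma_b2 = 0.5, N = 150,
#'                       size_profile = "fixed30", seed = 2)
#' fit <- fit_ghm(simulate_cohort(spec))
#' fit$sigma_b^2
#' @export
fit_ghm <- function(counts, n_quad = 25) {
  stopifnot(inherits(counts, "provider_counts"))
  if (nrow(counts) < 2L) stop("need at least 2 providers", call. = FALSE)
  key <- paste(counts$y, counts$n)
  u <- !duplicated(key)
  yu <- counts$y[u]
  nu <- counts$n[u]
  cnt <- as.vector(table(factor(key, levels = key[u])))

  negll <- function(par) {
    sb <- exp(par[2])
    if (!is.finite(sb) || sb > 50) return(1e10)
    v <- -sum(cnt * ghm_loglik_terms(par[1], sb, yu, nu, n_quad))
    if (!is.finite(v)) 1e10 else v
  }

  # method-of-moments start: remove mean binomial noise from the raw
  # variance, map to the logit scale by the delta method
  p <- counts$y / counts$n
  pbar <- min(max(mean(p), 1e-3), 1 - 1e-3)
  v_signal <- max(population_variance(p) - mean(p * (1 - p) / counts$n),
                  1e-5)
  s0 <- sqrt(v_signal) / (pbar * (1 - pbar))
  start <- c(logit(pbar), log(min(max(s0, 0.01), 5)))

  opt <- stats::optim(start, negll, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  if (opt$convergence != 0) {
    start2 <- start + stats::rnorm(2, 0, 0.25)
    opt2 <- stats::optim(start2, negll, method = "Nelder-Mead",
                         control = list(reltol = 1e-12, maxit = 4000))
    if (opt2$value < opt$value) opt <- opt2
  }
  if (opt$convergence != 0) {
    stop(sprintf(
      "GHM fit did not converge (best beta0 %.4f, sigma_b %.4f, loglik %.4f)",
      opt$par[1], exp(opt$par[2]), -opt$value), call. = FALSE)
  }
  sigma_b <- exp(opt$par[2])
  if (sigma_b < 1e-4) sigma_b <- 0  # boundary: no detectable heterogeneity
  structure(list(beta0 = opt$par[1], sigma_b = sigma_b,
                 loglik = -opt$value, n_quad = n_quad,
                 converged = TRUE),
            class = "ghm_fit")
}

#' @export
print.ghm_fit <- function(x, ...) {
  cat(sprintf(
    "Gaussian hierarchical model fit\n  beta0 %.4f  sigma_b^2 %.5f  loglik %.3f  (%d-node adaptive GH)\n",
    x$beta0, x$sigma_b^2, x$loglik, x$n_quad))
  invisible(x)
}

#' @export
coef.ghm_fit <- function(object, ...) {
  c(beta0 = object$beta0, sigma_b2 = object$sigma_b^2)
}

#' Logit-normal density implied by a Gaussian hierarchical model fit
#'
#' The model implies `p = expit(beta0 + sigma_b Z)`; on the probability
#' scale its law is logit-normal with closed-form density
#' `f(u) = phi((logit(u) - beta0)/sigma_b) / (sigma_b u (1-u))` and
#' distribution function `Phi((logit(u) - beta0)/sigma_b)`.
#'
#' @param fit a `ghm_fit`.
#' @param grid optional abscissae in (0,1); default 512 points covering
#'   `expit(beta0 +/- 6 sigma_b)`.
#' @return A [pdist] with `method = "ghm"`. A boundary fit
#'   (`sigma_b = 0`) yields a degenerate spike flagged by
#'   `$degenerate = TRUE`.
#' @export
ghm_density <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "ghm_fit"))
  m <- expit(fit$beta0)
  if (fit$sigma_b == 0) {
    h <- 1e-4
    grid <- grid %||% seq(max(m - 4 * h, 1e-9), min(m + 4 * h, 1 - 1e-9),
                          length.out = 512)
    pdf <- stats::dnorm(grid, m, h)  # narrow spike standing in for a point mass
    out <- new_pdist("ghm", mean = m, variance = 0, grid = grid, pdf = pdf,
                     cdf = function(x) as.numeric(x >= m), fit = fit,
                     degenerate = TRUE)
    return(out)
  }
  lo <- expit(fit$beta0 - 6 * fit$sigma_b)
  hi <- expit(fit$beta0 + 6 * fit$sigma_b)
  grid <- grid %||% seq(max(lo, 1e-9), min(hi, 1 - 1e-9), length.out = 512)
  pdf_fun <- function(u) {
    out <- numeric(length(u))
    ok <- u > 0 & u < 1
    out[ok] <- stats::dnorm((logit(u[ok]) - fit$beta0) / fit$sigma_b) /
      (fit$sigma_b * u[ok] * (1 - u[ok]))
    out
  }
  cdf <- function(x) {
    out <- numeric(length(x))
    out[x >= 1] <- 1
    ok <- x > 0 & x < 1
    out[ok] <- stats::pnorm((logit(x[ok]) - fit$beta0) / fit$sigma_b)
    out
  }
  mom <- ghm_moments(fit)
  new_pdist("ghm", mean = mom[["mean"]], variance = mom[["variance"]],
            grid = grid, pdf = pdf_fun(grid), cdf = cdf, fit = fit,
            pdf_fun = pdf_fun)
}

# mean and variance of expit(beta0 + sigma_b Z) by Gauss-Hermite quadrature,
# nodes doubled until the variance changes by < rel_tol
ghm_moments <- function(fit, n_nodes = 201, rel_tol = 1e-8) {
  if (fit$sigma_b == 0) {
    return(c(mean = expit(fit$beta0), variance = 0))
  }
  g <- function(z) expit(fit$beta0 + fit$sigma_b * z)
  repeat {
    m1 <- gauss_hermite_expect(g, n_nodes)
    m2 <- gauss_hermite_expect(function(z) g(z)^2, n_nodes)
    v1 <- m2 - m1^2
    m1d <- gauss_hermite_expect(g, 2 * n_nodes + 1)
    m2d <- gauss_hermite_expect(function(z) g(z)^2, 2 * n_nodes + 1)
    v2 <- m2d - m1d^2
    if (abs(v1 - v2) <= rel_tol * max(abs(v2), 1e-12) || n_nodes >= 1601) {
      return(c(mean = m1d, variance = v2))
    }
    n_nodes <- 2 * n_nodes + 1
  }
}

#' Variance of the fitted logit-normal provider distribution
#'
#' `Var[expit(beta0 + sigma_b Z)]`, `Z` standard normal, by Gauss-Hermite
#' quadrature with at least 201 nodes (doubled until stable to 1e-8
#' relative).
#'
#' @param fit a `ghm_fit`.
#' @return Nonnegative scalar.
#' @export
ghm_variance <- function(fit) {
  stopifnot(inherits(fit, "ghm_fit"))
  unname(ghm_moments(fit)[["variance"]])
}

#' Empirical-Bayes provider predictions from a Gaussian hierarchical fit
#'
#' Posterior means `E[expit(beta0 + sigma_b Z) | y_i]` under the fitted
#' Gaussian prior, by adaptive Gauss-Hermite quadrature. Included as the
#' over-shrunk comparator: the cross-provider spread of these predictions
#' understates the true provider-level variance.
#'
#' @param fit a `ghm_fit`.
#' @param counts the [provider_counts] the model was fitted to.
#' @param type posterior `"mean"` (default) or posterior `"mode"`
#'   (conventions differ across mixed-model software).
#' @return A [pdist] with `method = "ghm_eb"`; `support_points` are the
#'   per-provider predictions.
#' @export
eb_predictions <- function(fit, counts, type = c("mean", "mode")) {
  stopifnot(inherits(fit, "ghm_fit"), inherits(counts, "provider_counts"))
  type <- match.arg(type)
  key <- paste(counts$y, counts$n)
  u <- !duplicated(key)
  yu <- counts$y[u]
  nu <- counts$n[u]
  if (fit$sigma_b < 1e-8) {
    pb_u <- rep(expit(fit$beta0), length(yu))
  } else if (type == "mode") {
    pb_u <- expit(fit$beta0 + eb_posterior_modes(fit, yu, nu))
  } else {
    pb_u <- eb_posterior_means(fit, yu, nu)
  }
  pb <- pb_u[match(key, key[u])]
  if (max(pb) - min(pb) > 1e-10) {
    out <- kde(pb)
  } else {
    out <- kde(pb, bandwidth = 1e-4)
  }
  out$method <- "ghm_eb"
  out$fit <- fit
  out
}

eb_posterior_modes <- function(fit, y, n) {
  sigma_b <- fit$sigma_b
  b <- rep(0, length(y))
  for (it in 1:30) {
    p <- expit(fit$beta0 + b)
    g <- y - n * p - b / sigma_b^2
    h <- -n * p * (1 - p) - 1 / sigma_b^2
    b <- b - g / h
  }
  b
}

# posterior mean of expit(beta0 + b) given y, adaptive GH on the posterior
eb_posterior_means <- function(fit, y, n, n_quad = NULL) {
  n_quad <- n_quad %||% fit$n_quad
  sigma_b <- fit$sigma_b
  b <- eb_posterior_modes(fit, y, n)
  p <- expit(fit$beta0 + b)
  s <- 1 / sqrt(n * p * (1 - p) + 1 / sigma_b^2)
  r <- gh_rule(n_quad)
  bk <- outer(b, rep(1, n_quad)) + sqrt(2) * outer(s, r$x)
  eta <- fit$beta0 + bk
  logint <- y * eta - n * log1pexp(eta) +
    stats::dnorm(bk, 0, sigma_b, log = TRUE)
  lw <- matrix(log(r$w) + r$x^2, nrow = length(y), ncol = n_quad,
               byrow = TRUE)
  lognum <- logint + lw + log(expit(eta))
  logden <- logint + lw
  exp(apply(lognum, 1, logsumexp) - apply(logden, 1, logsumexp))
}
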