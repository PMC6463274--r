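## Semi-parametric Bayesian beta-binomial model with a Dirichlet-process
## prior on the distribution of provider probabilities:
##   Y_i | p_i ~ Binomial(n_i, p_i), p_i | F ~ F, F ~ DP(alpha F0),
##   F0 = Beta(a1, b1), alpha fixed or alpha ~ Gamma(a0, b0) (rate
##   parameterization, mean a0/b0).
## The Beta base is conjugate, so cluster parameters are integrated out and
## the partition is sampled by a collapsed (Polya-urn) Gibbs sampler.

#' Configuration of the Dirichlet-process beta-binomial model
#'
#' The concentration `alpha` controls the prior number of clusters of
#' providers sharing a probability: small `alpha` concentrates mass on few
#' clusters (all providers alike), large `alpha` approaches a fixed-effects
#' model. A Gamma hyper-prior on `alpha` (rate parameterization: mean
#' `a0/b0`) lets the data inform it. Presets match three specifications
#' used in provider-variation work: `dp1` (`a0 = 4, b0 = 4`, favoring
#' roughness: for 100 providers, 95% of the prior cluster-count mass falls
#' on 10 or fewer clusters), `dp2` (`a0 = 10, b0 = 0.10`, favoring
#' smoothness: prior mass between about 53 and 83 clusters), and `dp3`
#' (fixed `alpha = 20`).
#'
#' @param a1,b1 Beta base-measure parameters (default 1, 1 = Uniform(0,1)).
#' @param alpha fixed concentration; ignored when `a0`/`b0` given.
#' @param a0,b0 Gamma hyper-prior shape and rate for `alpha` (both or
#'   neither).
#' @param n_iter,burn_in,thin MCMC settings.
#' @param preset shortcut: `"dp1"`, `"dp2"` or `"dp3"` (overrides
#'   `alpha`/`a0`/`b0`).
#' @return A list of class `dp_config`.
#' @export
dp_config <- function(a1 = 1, b1 = 1, alpha = 1, a0 = NULL, b0 = NULL,
                      n_iter = 5000, burn_in = 1000, thin = 4,
                      preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("dp1", "dp2", "dp3"))
    if (preset == "dp1") { a0 <- 4; b0 <- 4; alpha <- NULL }
    if (preset == "dp2") { a0 <- 10; b0 <- 0.10; alpha <- NULL }
    if (preset == "dp3") { alpha <- 20; a0 <- NULL; b0 <- NULL }
  }
  hyper <- !is.null(a0) || !is.null(b0)
  if (hyper && (is.null(a0) || is.null(b0))) {
    stop("supply both a0 and b0 for the gamma hyper-prior", call. = FALSE)
  }
  if (a1 <= 0 || b1 <= 0) stop("a1, b1 must be positive", call. = FALSE)
  if (hyper && (a0 <= 0 || b0 <= 0)) {
    stop("a0, b0 must be positive", call. = FALSE)
  }
  if (!hyper && (is.null(alpha) || alpha <= 0)) {
    stop("alpha must be positive", call. = FALSE)
  }
  if (n_iter <= burn_in || burn_in < 0 || thin < 1) {
    stop("require n_iter > burn_in >= 0 and thin >= 1", call. = FALSE)
  }
  structure(list(a1 = a1, b1 = b1,
                 alpha = if (hyper) NULL else alpha,
                 a0 = a0, b0 = b0, hyper = hyper,
                 n_iter = n_iter, burn_in = burn_in, thin = thin),
            class = "dp_config")
}

# log beta-binomial marginal of (y, n) under Beta(a, b)
lbetabinom <- function(y, n, a, b) {
  lchoose(n, y) + lbeta(a + y, b + n - y) - lbeta(a, b)
}

#' Fit the Dirichlet-process beta-binomial model by collapsed Gibbs sampling
#'
#' Polya-urn Gibbs over cluster assignments: provider `i` joins an existing
#' cluster with probability proportional to the cluster size (without `i`)
#' times the beta-binomial marginal of `y_i` given the cluster's other
#' members, and opens a new cluster with probability proportional to
#' `alpha` times the prior marginal. With a Gamma hyper-prior, `alpha` is
#' refreshed each sweep by the standard beta-augmentation conditional
#' (a two-component Gamma mixture given the number of occupied clusters).
#'
#' @param counts a [provider_counts] object.
#' @param config a [dp_config].
#' @param seed integer seed; draws are reproducible given (seed, config).
#' @param prior_only if TRUE the likelihood is switched off (all marginals
#'   constant), so the sampler explores the prior over partitions;
#'   a validation device for checking prior cluster-count recovery.
#' @return An object of class `dp_fit`: `labels` (retained draws x N
#'   cluster-assignment matrix), `cluster_counts`, `alphas`, `config`.
#' @export
dp_fit <- function(counts, config = dp_config(), seed = 1,
                   prior_only = FALSE) {
  stopifnot(inherits(counts, "provider_counts"),
            inherits(config, "dp_config"))
  y <- counts$y
  n <- counts$n
  N <- length(y)
  a1 <- config$a1
  b1 <- config$b1
  with_seed(seed, {
    alpha <- if (config$hyper) stats::rgamma(1, config$a0, config$b0)
             else config$alpha
    # state: z (labels 1..K), per-cluster sums of y and n-y, sizes
    z <- rep(1L, N)
    cs_y <- sum(y)
    cs_f <- sum(n - y)
    csize <- N
    K <- 1L
    keep <- seq(config$burn_in + 1L, config$n_iter, by = config$thin)
    labels <- matrix(NA_integer_, nrow = length(keep), ncol = N)
    alphas <- numeric(length(keep))
    kk <- 0L
    lmarg0 <- if (prior_only) rep(0, N) else lbetabinom(y, n, a1, b1)
    for (it in seq_len(config$n_iter)) {
      for (i in seq_len(N)) {
        zi <- z[i]
        csize[zi] <- csize[zi] - 1L
        cs_y[zi] <- cs_y[zi] - y[i]
        cs_f[zi] <- cs_f[zi] - (n[i] - y[i])
        if (csize[zi] == 0L) {
          # remove empty cluster, relabel the last one into its slot
          csize[zi] <- csize[K]; cs_y[zi] <- cs_y[K]; cs_f[zi] <- cs_f[K]
          z[z == K] <- zi
          csize <- csize[-K]; cs_y <- cs_y[-K]; cs_f <- cs_f[-K]
          K <- K - 1L
        }
        if (prior_only) {
          lm <- rep(0, K)
        } else {
          lm <- lbetabinom(y[i], n[i], a1 + cs_y, b1 + cs_f)
        }
        logw <- c(log(csize) + lm, log(alpha) + lmarg0[i])
        w <- exp(logw - max(logw))
        pick <- sample.int(K + 1L, 1L, prob = w)
        if (pick > K) {
          K <- K + 1L
          csize <- c(csize, 1L)
          cs_y <- c(cs_y, y[i])
          cs_f <- c(cs_f, n[i] - y[i])
          z[i] <- K
        } else {
          z[i] <- pick
          csize[pick] <- csize[pick] + 1L
          cs_y[pick] <- cs_y[pick] + y[i]
          cs_f[pick] <- cs_f[pick] + (n[i] - y[i])
        }
      }
      if (config$hyper) {
        # beta augmentation for the concentration parameter
        eta <- stats::rbeta(1, alpha + 1, N)
        odds <- (config$a0 + K - 1) / (N * (config$b0 - log(eta)))
        shape <- if (stats::runif(1) < odds / (1 + odds)) config$a0 + K
                 else config$a0 + K - 1
        alpha <- stats::rgamma(1, shape, config$b0 - log(eta))
      }
      if (it %in% keep) {
        kk <- kk + 1L
        labels[kk, ] <- z
        alphas[kk] <- alpha
      }
    }
    structure(list(labels = labels,
                   cluster_counts = apply(labels, 1,
                                          function(r) length(unique(r))),
                   alphas = alphas, config = config, seed = seed,
                   prior_only = prior_only),
              class = "dp_fit")
  })
}

#' @export
print.dp_fit <- function(x, ...) {
  cat(sprintf(
    "DP beta-binomial fit: %d retained draws, %d providers\n  clusters: median %g (95%% %g-%g); alpha: median %.3g\n",
    nrow(x$labels), ncol(x$labels),
    stats::median(x$cluster_counts),
    stats::quantile(x$cluster_counts, 0.025),
    stats::quantile(x$cluster_counts, 0.975),
    stats::median(x$alphas)))
  invisible(x)
}

#' Rao-Blackwellized posterior density of the provider probability
#'
#' For each retained draw the conditional predictive of a new provider
#' probability is an explicit mixture of Beta densities,
#' `alpha/(alpha+N) Beta(a1, b1) + sum_c n_c/(alpha+N) Beta(a1 + sum y,
#' b1 + sum (n-y))`; averaging over draws gives a smooth posterior density
#' estimate whose integral against `u` and `(u - mean)^2` yield the
#' posterior mean and variance.
#'
#' @param result a `dp_fit`.
#' @param counts the [provider_counts] it was fitted to.
#' @param grid abscissae in (0,1) (default 512 interior points).
#' @return A [pdist] with `method = "dp"`.
#' @export
dp_density <- function(result, counts, grid = NULL) {
  stopifnot(inherits(result, "dp_fit"), inherits(counts, "provider_counts"))
  y <- counts$y
  n <- counts$n
  N <- length(y)
  a1 <- result$config$a1
  b1 <- result$config$b1
  ndraw <- nrow(result$labels)
  # accumulate mixture components over draws: weight, shape1, shape2
  comp_w <- comp_a <- comp_b <- vector("list", ndraw + 1L)
  for (d in seq_len(ndraw)) {
    z <- result$labels[d, ]
    alpha <- result$alphas[d]
    ay <- tapply(y, z, sum)
    af <- tapply(n - y, z, sum)
    nc <- tabulate(z)
    nc <- nc[nc > 0]
    comp_w[[d]] <- c(alpha, nc) / (alpha + N) / ndraw
    comp_a[[d]] <- c(a1, a1 + ay)
    comp_b[[d]] <- c(b1, b1 + af)
  }
  w <- unlist(comp_w)
  sa <- unlist(comp_a)
  sb <- unlist(comp_b)
  pdf_fun <- function(u) {
    vapply(u, function(ui) {
      if (ui <= 0 || ui >= 1) return(0)
      sum(w * stats::dbeta(ui, sa, sb))
    }, numeric(1))
  }
  cdf <- function(x) {
    vapply(x, function(xi) sum(w * stats::pbeta(xi, sa, sb)), numeric(1))
  }
  grid <- grid %||% seq(1 / 1024, 1 - 1 / 1024, length.out = 512)
  mu <- sum(w * sa / (sa + sb))
  ex2 <- sum(w * (sa * (sa + 1)) / ((sa + sb) * (sa + sb + 1)))
  new_pdist("dp", mean = mu, variance = ex2 - mu^2, grid = grid,
            pdf = pdf_fun(grid), cdf = cdf, fit = result,
            pdf_fun = pdf_fun)
}

#' Prior distribution of the number of clusters under a DP
#'
#' Simulates the prior number of distinct clusters among `N` providers:
#' `alpha` is drawn from its Gamma hyper-prior (or held fixed) and the
#' Chinese-restaurant process seated for `N` customers. The number of
#' distinct tables equals the sum of independent new-table indicators
#' `Bernoulli(alpha / (alpha + i - 1))`, which is sampled directly. Used to
#' calibrate hyper-prior choices against the intended prior smoothness.
#'
#' @param N number of providers.
#' @param config a [dp_config] (only the alpha specification is used).
#' @param n_draws Monte Carlo draws (>= 1000).
#' @param seed integer seed.
#' @return An object of class `dp_prior_clusters`: list with `counts`
#'   (draws), `table` (empirical pmf), and `quantile(p)` convenience via
#'   [stats::quantile()] on `$counts`.
#' @examples
#' pr <- prior_cluster_distribution(100, dp_config(preset = "dp1"),
#'                                  n_draws = 2000, seed = 1)
#' quantile(pr$counts, 0.95)
#' @export
prior_cluster_distribution <- function(N, config, n_draws = 20000,
                                       seed = 1) {
  stopifnot(inherits(config, "dp_config"))
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  if (n_draws < 1000) stop("n_draws must be >= 1000", call. = FALSE)
  with_seed(seed, {
    alpha <- if (config$hyper) stats::rgamma(n_draws, config$a0, config$b0)
             else rep(config$alpha, n_draws)
    # P(new table at customer i) = alpha / (alpha + i - 1), independent
    K <- rep(1L, n_draws)
    if (N > 1) {
      for (i in 2:N) {
        K <- K + (stats::runif(n_draws) < alpha / (alpha + i - 1))
      }
    }
    tab <- table(factor(K, levels = seq_len(max(K))))
    structure(list(counts = as.integer(K),
                   table = data.frame(k = as.integer(names(tab)),
                                      probability = as.numeric(tab) / n_draws),
                   N = N, n_draws = n_draws, seed = seed, config = config),
              class = "dp_prior_clusters")
  })
}

#' @export
print.dp_prior_clusters <- function(x, ...) {
  q <- stats::quantile(x$counts, c(0.025, 0.5, 0.95, 0.975), type = 1)
  cat(sprintf(
    "Prior clusters for N=%d (%d draws): median %g, 95th pctile %g, central 95%% [%g, %g]\n",
    x$N, x$n_draws, q[2], q[3], q[1], q[4]))
  invisible(x)
}
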