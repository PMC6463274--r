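## Generative truths for method evaluation: provider probabilities are
## p_i = expit(beta0 + b_i) with b_i drawn from one of three laws on the
## logit scale (all standardized to mean 0, variance sigma_b2):
##   normal  - Normal(0, sigma_b2)
##   chisq   - sigma_b (V - 1)/sqrt(2), V ~ chi-square(1) (skewness 2*sqrt2)
##   bimodal - equal mixture of Normal(-delta, tau^2) and Normal(delta,
##             tau^2) with delta/tau = 2 and delta^2 + tau^2 = sigma_b2
## Outcomes are y_i ~ Binomial(n_i, p_i). Site sizes follow fixed or
## registry-like / trial-like profiles (truncated, rounded lognormals
## calibrated to printed median/IQR targets).

# calibrated lognormal size profiles (see scratch calibration): values are
# resampled below 10, then rounded
.size_profiles <- list(
  trial = c(meanlog = 2.981499, sdlog = 0.884845),     # median ~25, IQR ~17-43
  registry = c(meanlog = 4.168437, sdlog = 0.914024)   # median ~65, IQR ~38-126
)

#' Specify a generative scenario
#'
#' @param law logit-scale random-effect law: `"normal"`, `"chisq"` or
#'   `"bimodal"`.
#' @param sigma_b2 logit-scale variance (> 0); 0.05 and 0.50 are the
#'   "small" and "large" presets used throughout.
#' @param beta0 intercept on the logit scale; default `logit(0.25)`,
#'   representative of early-follow-up rates in the motivating registry
#'   data (raw rates between roughly 20% and 33%).
#' @param N number of providers (>= 2).
#' @param size_profile `"fixed20"`, `"fixed30"`, `"trial"` (median ~25, IQR
#'   17-43), `"registry"` (median ~65, IQR 38-126), or an explicit integer
#'   vector of length `N`.
#' @param seed integer seed; all generation is deterministic given it.
#' @return An object of class `scenario_spec`.
#' @examples
#' spec <- scenario_spec("chisq", sigma_b2 = 0.5, N = 300,
#'                       size_profile = "fixed30", seed = 1)
#' true_variance(spec)
#' @export
scenario_spec <- function(law = c("normal", "chisq", "bimodal"),
                          sigma_b2 = 0.05, beta0 = stats::qlogis(0.25),
                          N = 300, size_profile = "fixed30", seed = 1) {
  law <- match.arg(law)
  if (sigma_b2 <= 0) stop("sigma_b2 must be > 0", call. = FALSE)
  if (N < 2) stop("N must be >= 2", call. = FALSE)
  if (is.character(size_profile)) {
    size_profile <- match.arg(size_profile,
                              c("fixed20", "fixed30", "trial", "registry"))
  } else {
    size_profile <- as.integer(size_profile)
    if (length(size_profile) != N || any(size_profile < 1)) {
      stop("explicit size_profile must be N positive integers",
           call. = FALSE)
    }
  }
  structure(list(law = law, sigma_b2 = sigma_b2, beta0 = beta0, N = N,
                 size_profile = size_profile, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "scenario: %s logit effects, sigma_b2 %g, beta0 %.4f, N %d, sizes %s, seed %d\n",
    x$law, x$sigma_b2, x$beta0, x$N,
    if (is.character(x$size_profile)) x$size_profile else "explicit",
    x$seed))
  cat(sprintf("  true provider variance %.6f\n", true_variance(x)))
  invisible(x)
}

# mixture constants for the bimodal law
bimodal_pars <- function(sigma_b2) {
  tau <- sqrt(sigma_b2 / 5)  # delta = 2 tau, delta^2 + tau^2 = sigma_b2
  c(delta = 2 * tau, tau = tau)
}

# draw b_i for a spec (no seed handling; caller controls RNG)
draw_b <- function(spec, N) {
  sb <- sqrt(spec$sigma_b2)
  switch(spec$law,
    normal = stats::rnorm(N, 0, sb),
    chisq = sb * (stats::rchisq(N, df = 1) - 1) / sqrt(2),
    bimodal = {
      p <- bimodal_pars(spec$sigma_b2)
      sgn <- ifelse(stats::runif(N) < 0.5, -1, 1)
      stats::rnorm(N, sgn * p[["delta"]], p[["tau"]])
    })
}

#' Generate provider probabilities from a scenario
#'
#' @param spec a [scenario_spec].
#' @param N optionally override the provider count.
#' @return Numeric vector `p_1..p_N` in (0,1), deterministic given the
#'   spec's seed.
#' @export
gen_provider_probs <- function(spec, N = spec$N) {
  stopifnot(inherits(spec, "scenario_spec"))
  with_seed(spec$seed, expit(spec$beta0 + draw_b(spec, N)))
}

#' Generate per-provider patient counts from a scenario
#'
#' Fixed profiles return constants; `trial` and `registry` draw from
#' truncated-at-10, rounded lognormals calibrated so the resulting
#' median/IQR match the respective targets (about 25 with IQR 17-43, and
#' 65 with IQR 38-126).
#'
#' @param spec a [scenario_spec].
#' @param N optionally override the provider count.
#' @return Integer vector `n_1..n_N`, deterministic given the spec's seed.
#' @export
gen_cluster_sizes <- function(spec, N = spec$N) {
  stopifnot(inherits(spec, "scenario_spec"))
  sp <- spec$size_profile
  if (!is.character(sp)) return(rep_len(sp, N))
  if (sp == "fixed20") return(rep(20L, N))
  if (sp == "fixed30") return(rep(30L, N))
  pars <- .size_profiles[[sp]]
  with_seed(spec$seed + 1L, {
    plo <- stats::plnorm(10, pars[["meanlog"]], pars[["sdlog"]])
    u <- stats::runif(N, plo, 1)  # truncation below 10 by inverse-cdf
    pmax(10L, as.integer(round(stats::qlnorm(u, pars[["meanlog"]],
                                             pars[["sdlog"]]))))
  })
}

#' Generate binomial outcomes
#'
#' @param p provider probabilities.
#' @param n patient counts (same length).
#' @param seed integer seed.
#' @param provider_id optional labels (default `site_1..site_N`).
#' @return A [provider_counts] with `y_i ~ Binomial(n_i, p_i)`.
#' @export
gen_outcomes <- function(p, n, seed, provider_id = NULL) {
  stopifnot(length(p) == length(n))
  provider_id <- provider_id %||% paste0("site_", seq_along(p))
  y <- with_seed(seed, stats::rbinom(length(p), n, p))
  provider_counts(provider_id, y, n)
}

#' Simulate a full cohort from a scenario
#'
#' Convenience composition of [gen_provider_probs()], [gen_cluster_sizes()]
#' and [gen_outcomes()]; the true probabilities are attached as attribute
#' `"p"`.
#'
#' @param spec a [scenario_spec].
#' @return A [provider_counts].
#' @export
simulate_cohort <- function(spec) {
  p <- gen_provider_probs(spec)
  n <- gen_cluster_sizes(spec)
  out <- gen_outcomes(p, n, seed = spec$seed + 2L)
  attr(out, "p") <- p
  out
}

# density of b on the logit scale
b_density <- function(spec, b) {
  sb <- sqrt(spec$sigma_b2)
  switch(spec$law,
    normal = stats::dnorm(b, 0, sb),
    chisq = {
      # b = sb (V-1)/sqrt2, V ~ chi2_1; support b >= -sb/sqrt2
      v <- 1 + sqrt(2) * b / sb
      out <- numeric(length(b))
      ok <- v > 0
      out[ok] <- stats::dchisq(v[ok], df = 1) * sqrt(2) / sb
      out
    },
    bimodal = {
      p <- bimodal_pars(spec$sigma_b2)
      0.5 * stats::dnorm(b, -p[["delta"]], p[["tau"]]) +
        0.5 * stats::dnorm(b, p[["delta"]], p[["tau"]])
    })
}

b_cdf <- function(spec, b) {
  sb <- sqrt(spec$sigma_b2)
  switch(spec$law,
    normal = stats::pnorm(b, 0, sb),
    chisq = {
      v <- 1 + sqrt(2) * b / sb
      out <- numeric(length(b))
      ok <- v > 0
      out[ok] <- stats::pchisq(v[ok], df = 1)
      out
    },
    bimodal = {
      p <- bimodal_pars(spec$sigma_b2)
      0.5 * stats::pnorm(b, -p[["delta"]], p[["tau"]]) +
        0.5 * stats::pnorm(b, p[["delta"]], p[["tau"]])
    })
}

#' Exact density of the provider probability under a scenario
#'
#' Change of variables from the logit-scale law: for `u` in (0,1),
#' `f_p(u) = f_b(logit(u) - beta0) / (u (1 - u))`. The chi-square law has a
#' one-sided support bound on `b`; the density is 0 beyond it.
#'
#' @param spec a [scenario_spec].
#' @param grid abscissae in (0,1).
#' @return Density values on `grid`.
#' @export
true_density <- function(spec, grid) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (any(grid <= 0 | grid >= 1)) {
    stop("density grid points must lie in (0,1)", call. = FALSE)
  }
  b_density(spec, logit(grid) - spec$beta0) / (grid * (1 - grid))
}

#' Exact distribution function of the provider probability
#'
#' @param spec a [scenario_spec].
#' @param x evaluation points in `[0, 1]` (values outside clamp to 0/1).
#' @return CDF values.
#' @export
true_cdf <- function(spec, x) {
  stopifnot(inherits(spec, "scenario_spec"))
  out <- numeric(length(x))
  out[x >= 1] <- 1
  ok <- x > 0 & x < 1
  out[ok] <- b_cdf(spec, logit(x[ok]) - spec$beta0)
  out
}

#' Exact variance of the provider probability
#'
#' `Var[expit(beta0 + b)]` by quadrature. The normal and bimodal laws use
#' Gauss-Hermite in the (component) normal variable; the chi-square law is
#' rewritten as `b = sigma_b (Z^2 - 1)/sqrt(2)` with `Z` standard normal,
#' which makes the integrand smooth. Relative tolerance 1e-8 via node
#' doubling.
#'
#' @param spec a [scenario_spec].
#' @return Nonnegative scalar.
#' @export
true_variance <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  true_moments(spec)[["variance"]]
}

true_moments <- function(spec, n_nodes = 401) {
  sb <- sqrt(spec$sigma_b2)
  g <- switch(spec$law,
    normal = function(z) expit(spec$beta0 + sb * z),
    chisq = function(z) expit(spec$beta0 + sb * (z^2 - 1) / sqrt(2)),
    bimodal = NULL)
  if (spec$law == "bimodal") {
    p <- bimodal_pars(spec$sigma_b2)
    ex <- function(k, nn) {
      0.5 * gauss_hermite_expect(function(z)
        expit(spec$beta0 - p[["delta"]] + p[["tau"]] * z)^k, nn) +
      0.5 * gauss_hermite_expect(function(z)
        expit(spec$beta0 + p[["delta"]] + p[["tau"]] * z)^k, nn)
    }
  } else {
    ex <- function(k, nn) gauss_hermite_expect(function(z) g(z)^k, nn)
  }
  nn <- n_nodes
  repeat {
    v1 <- ex(2, nn) - ex(1, nn)^2
    v2 <- ex(2, 2 * nn + 1) - ex(1, 2 * nn + 1)^2
    if (abs(v1 - v2) <= 1e-8 * max(abs(v2), 1e-12) || nn >= 3201) {
      return(c(mean = ex(1, 2 * nn + 1), variance = v2))
    }
    nn <- 2 * nn + 1
  }
}

#' Export a simulated cohort with its generative truth
#'
#' Writes the counts CSV and a truth JSON (`law`, `sigma_b2`, `beta0`,
#' `true_variance`, seed) so downstream comparisons never re-derive the
#' truth inconsistently.
#'
#' @param spec a [scenario_spec].
#' @param counts_path CSV path for the counts.
#' @param truth_path JSON path for the truth (NULL to skip).
#' @return The simulated [provider_counts], invisibly.
#' @export
export_cohort <- function(spec, counts_path, truth_path = NULL) {
  pc <- simulate_cohort(spec)
  write_counts(pc, counts_path)
  if (!is.null(truth_path)) {
    jsonlite::write_json(
      list(law = spec$law, sigma_b2 = spec$sigma_b2, beta0 = spec$beta0,
           N = spec$N,
           size_profile = if (is.character(spec$size_profile))
             spec$size_profile else "explicit",
           seed = spec$seed, true_variance = true_variance(spec)),
      truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(pc)
}
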