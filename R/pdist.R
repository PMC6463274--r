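#' Estimated provider-probability distribution
#'
#' All estimators in the package return a `pdist` object describing an
#' estimated law of the latent provider probability: its mean and variance,
#' a density evaluated on a grid, a distribution-function evaluator, and the
#' per-provider values underlying the estimate where the method produces any.
#'
#' @section Structure:
#' A list with elements `method` (one of `raw`, `ghm`, `ghm_eb`, `mai`,
#' `sbr`, `dp`), `mean`, `variance`, `grid` (strictly increasing abscissae),
#' `pdf` (nonnegative density values on `grid`), `cdf` (vectorized
#' nondecreasing function on [0,1]), `support_points` (optional numeric
#' vector), and `fit` (the method-specific fit object, if any). Kernel
#' density grids may spill slightly outside [0,1] (Gaussian kernel tails);
#' the recorded grid is the actual one and no truncation is applied.
#'
#' @name pdist
NULL

new_pdist <- function(method, mean, variance, grid, pdf, cdf,
                      support_points = NULL, fit = NULL, ...) {
  stopifnot(is.function(cdf), length(grid) == length(pdf))
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("pdist grid must be strictly increasing", call. = FALSE)
  }
  if (any(pdf < 0)) stop("pdist pdf must be nonnegative", call. = FALSE)
  structure(
    c(list(method = method, mean = mean, variance = variance, grid = grid,
           pdf = pdf, cdf = cdf, support_points = support_points, fit = fit),
      list(...)),
    class = "pdist")
}

#' Fit an estimator of the provider-probability distribution
#'
#' Front end dispatching to the individual estimators: `raw` sample
#' proportions ([raw_estimate()]), the Gaussian hierarchical model (`ghm`,
#' [fit_ghm()] + [ghm_density()]), its empirical-Bayes predictions
#' (`ghm_eb`, [eb_predictions()]), moment-adjusted imputation (`mai`,
#' [mai_estimate()]), smoothing by roughening (`sbr`, [sbr_fit()]), and the
#' Dirichlet-process beta-binomial mixture (`dp`, [dp_fit()]).
#'
#' @param counts a [provider_counts] object.
#' @param method estimator tag.
#' @param ... passed to the underlying estimator (e.g. `M` for `mai`,
#'   `nu_N` for `sbr`, `config` for `dp`).
#' @return A [pdist] object.
#' @examples
#' spec <- scenario_spec(law = "normal", sigma_b2 = 0.05, N = 100,
#'                       size_profile = "fixed30", seed = 1)
#' pc <- simulate_cohort(spec)
#' fit <- fit_pdist(pc, method = "mai")
#' summary(fit)
#' @export
fit_pdist <- function(counts,
                      method = c("raw", "ghm", "ghm_eb", "mai", "sbr", "dp"),
                      ...) {
  method <- match.arg(method)
  switch(method,
    raw = raw_estimate(counts, ...),
    ghm = ghm_density(fit_ghm(counts, ...)),
    ghm_eb = {
      fit <- fit_ghm(counts, ...)
      eb_predictions(fit, counts)
    },
    mai = mai_estimate(counts, ...),
    sbr = sbr_estimate(sbr_fit(counts, ...)),
    dp = {
      args <- list(...)
      config <- args$config %||% dp_config()
      res <- do.call(dp_fit, c(list(counts = counts, config = config),
                               args[setdiff(names(args), "config")]))
      dp_density(res, counts)
    })
}

#' @export
print.pdist <- function(x, ...) {
  cat(sprintf("pdist [%s]: mean %.4f, variance %.6f (sd %.4f)\n",
              x$method, x$mean, x$variance, sqrt(x$variance)))
  invisible(x)
}

#' @export
summary.pdist <- function(object, probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                          ...) {
  qs <- vapply(probs, function(p) pdist_quantile(object, p), numeric(1))
  out <- list(method = object$method, mean = object$mean,
              variance = object$variance, sd = sqrt(object$variance),
              quantiles = stats::setNames(qs, paste0(100 * probs, "%")),
              n_support = length(object$support_points))
  class(out) <- "summary.pdist"
  out
}

#' @export
print.summary.pdist <- function(x, ...) {
  cat(sprintf("Estimated provider-probability distribution (method: %s)\n",
              x$method))
  cat(sprintf("  mean %.4f  variance %.6f  sd %.4f\n", x$mean, x$variance,
              x$sd))
  cat("  quantiles:\n")
  print(round(x$quantiles, 4))
  invisible(x)
}

#' @export
coef.pdist <- function(object, ...) {
  out <- c(mean = object$mean, variance = object$variance)
  if (!is.null(object$fit) && inherits(object$fit, "ghm_fit")) {
    out <- c(out, beta0 = object$fit$beta0, sigma_b = object$fit$sigma_b)
  }
  out
}

# Inverse of the cdf by monotone bisection on [lo, hi].
pdist_quantile <- function(object, p, lo = NULL, hi = NULL) {
  lo <- lo %||% max(min(object$grid), 1e-12)
  hi <- hi %||% min(max(object$grid), 1 - 1e-12)
  if (object$cdf(lo) >= p) return(lo)
  if (object$cdf(hi) <= p) return(hi)
  stats::uniroot(function(x) object$cdf(x) - p, c(lo, hi),
                 tol = 1e-9)$root
}

#' Evaluate an estimated distribution
#'
#' @param object a [pdist] object.
#' @param x abscissae at which to evaluate.
#' @param type `"density"` (linear interpolation of the grid density, 0
#'   outside the grid) or `"cdf"`.
#' @param ... unused.
#' @return Numeric vector of the same length as `x`.
#' @export
predict.pdist <- function(object, x, type = c("density", "cdf"), ...) {
  type <- match.arg(type)
  if (type == "cdf") return(object$cdf(x))
  stats::approx(object$grid, object$pdf, xout = x, yleft = 0, yright = 0,
                rule = 1)$y
}

#' Draw from an estimated distribution
#'
#' Inverse-cdf sampling from the estimate's distribution-function evaluator.
#'
#' @param object a [pdist] object.
#' @param nsim number of draws.
#' @param seed optional integer seed.
#' @param ... unused.
#' @export
simulate.pdist <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() {
    u <- stats::runif(nsim)
    vapply(u, function(ui) pdist_quantile(object, ui), numeric(1))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' @export
plot.pdist <- function(x, truth = NULL, main = NULL, ...) {
  main <- main %||% sprintf("Estimated provider-probability density (%s)",
                            x$method)
  graphics::plot(x$grid, x$pdf, type = "l", xlab = "provider probability",
                 ylab = "density", main = main, ...)
  if (!is.null(truth)) {
    g <- x$grid[x$grid > 0 & x$grid < 1]
    graphics::lines(g, true_density(truth, g), lty = 2)
    graphics::legend("topright", legend = c(x$method, "truth"),
                     lty = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' Export an estimate's density and summary
#'
#' Writes the density grid as CSV (`grid,pdf`) and, optionally, a JSON
#' summary (method, mean, variance, plus method-specific fields).
#'
#' @param estimate a [pdist] object.
#' @param csv path for the density CSV (NULL to skip).
#' @param json path for the summary JSON (NULL to skip).
#' @return invisible list of the paths written.
#' @export
export_pdist <- function(estimate, csv = NULL, json = NULL) {
  stopifnot(inherits(estimate, "pdist"))
  if (!is.null(csv)) {
    utils::write.csv(data.frame(grid = estimate$grid, pdf = estimate$pdf),
                     csv, row.names = FALSE)
  }
  if (!is.null(json)) {
    s <- list(method = estimate$method, mean = estimate$mean,
              variance = estimate$variance)
    if (!is.null(estimate$bandwidth)) s$bandwidth <- estimate$bandwidth
    f <- estimate$fit
    if (inherits(f, "ghm_fit")) {
      s <- c(s, list(beta0 = f$beta0, sigma_b2 = f$sigma_b^2,
                     n_quad = f$n_quad, loglik = f$loglik))
    }
    if (inherits(f, "mai_fit")) {
      s <- c(s, list(M = f$M, multipliers = f$multipliers,
                     target_moments = f$target_moments,
                     max_constraint_violation = f$max_constraint_violation,
                     frac_outside_unit = f$frac_outside_unit))
    }
    jsonlite::write_json(s, json, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(csv = csv, json = json))
}
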