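## Smoothing by roughening: nonparametric empirical Bayes estimation of the
## mixing distribution of provider probabilities. Starting from a discrete
## uniform prior on a fine grid, each EM step
##   f_{v+1}(a_m) = N^-1 sum_i f(Y_i|a_m) f_v(a_m) / sum_m f(Y_i|a_m) f_v(a_m)
## moves the prior toward the nonparametric MLE; stopping after a finite
## number of iterations retains smoothness (the NPML itself is discrete and
## under-dispersed).

#' Fit the smoothing-by-roughening estimator
#'
#' Runs exactly `nu_N` EM updates of a discretized prior from a uniform
#' start on `M` grid points (midpoints of equal-width bins of `[0, 1]`). All
#' iterates are retained so sensitivity to the stopping iteration can be
#' inspected; iterated far enough the weights converge to the NPML
#' estimate. The `N x M` likelihood matrix is computed once, in log space,
#' and reused across iterations.
#'
#' The default `nu_N = 50` performs well across the simulation scenarios
#' the package targets; published guidance for small or moderate samples
#' suggests the range `N/3` to `2N`, and no stopping rule is universally
#' best, so plotting `sbr_estimate()` across several iterations is
#' recommended.
#'
#' @param counts a [provider_counts] object.
#' @param M number of grid mass points (>= 50).
#' @param nu_N number of EM iterations (>= 0).
#' @return An object of class `sbr_fit`: list with `grid`,
#'   `weights_by_iteration` (`(nu_N + 1) x M` matrix, row `v + 1` holds
#'   iterate `v`), `nu_N`, `M`, `loglik_by_iteration` (marginal
#'   log-likelihood of each iterate; nondecreasing by EM monotonicity).
#' @examples
#' pc <- provider_counts(1:3, y = c(1, 5, 9), n = c(10, 10, 10))
#' fit <- sbr_fit(pc, M = 100, nu_N = 20)
#' sbr_estimate(fit)$variance
#' @export
sbr_fit <- function(counts, M = 500, nu_N = 50) {
  stopifnot(inherits(counts, "provider_counts"))
  if (M < 50) stop("M must be >= 50", call. = FALSE)
  if (nu_N < 0) stop("nu_N must be >= 0", call. = FALSE)
  a <- (seq_len(M) - 0.5) / M
  # log f(Y_i | a_m), N x M
  logL <- outer(seq_len(nrow(counts)), seq_len(M), function(i, m) {
    stats::dbinom(counts$y[i], counts$n[i], a[m], log = TRUE)
  })
  f <- rep(1 / M, M)
  W <- matrix(NA_real_, nrow = nu_N + 1L, ncol = M)
  ll <- numeric(nu_N + 1L)
  W[1L, ] <- f
  ll[1L] <- sbr_loglik(logL, f)
  if (nu_N > 0) {
    for (v in seq_len(nu_N)) {
      lr <- sweep(logL, 2, log(f), `+`)          # log f(Y_i | a_m) f(a_m)
      rm <- apply(lr, 1, max)
      A <- exp(lr - rm)
      post <- A / rowSums(A)                     # posterior over grid per provider
      f <- colMeans(post)
      f <- f / sum(f)                            # guard rounding drift
      W[v + 1L, ] <- f
      ll[v + 1L] <- sbr_loglik(logL, f)
    }
  }
  # EM guarantees ascent of the marginal likelihood; tolerate only rounding
  if (nu_N > 0 && any(diff(ll) < -1e-8)) {
    stop("internal error: SBR marginal likelihood decreased", call. = FALSE)
  }
  structure(list(grid = a, weights_by_iteration = W, nu_N = nu_N, M = M,
                 loglik_by_iteration = ll),
            class = "sbr_fit")
}

sbr_loglik <- function(logL, f) {
  lr <- sweep(logL, 2, log(f), `+`)
  sum(apply(lr, 1, logsumexp))
}

#' @export
print.sbr_fit <- function(x, ...) {
  est <- sbr_estimate(x)
  cat(sprintf(
    "SBR fit: %d grid points, %d EM iterations\n  final mean %.4f, variance %.6f, loglik %.3f\n",
    x$M, x$nu_N, est$mean, est$variance,
    x$loglik_by_iteration[x$nu_N + 1L]))
  invisible(x)
}

#' Distribution estimate from an SBR iterate
#'
#' Mean and variance of the discrete prior at the requested iteration; the
#' density is the weights divided by the bin width (piecewise constant),
#' the distribution function the cumulative weights.
#'
#' @param result an `sbr_fit`.
#' @param at_iteration iterate to summarize, `0..nu_N` (default `nu_N`).
#' @return A [pdist] with `method = "sbr"`.
#' @export
sbr_estimate <- function(result, at_iteration = NULL) {
  stopifnot(inherits(result, "sbr_fit"))
  v <- at_iteration %||% result$nu_N
  if (v < 0 || v > result$nu_N) {
    stop("at_iteration out of range", call. = FALSE)
  }
  f <- result$weights_by_iteration[v + 1L, ]
  a <- result$grid
  mu <- sum(a * f)
  s2 <- sum((a - mu)^2 * f)
  width <- 1 / result$M
  cw <- cumsum(f)
  cdf <- function(x) {
    # mass point a_m counted once x passes it
    idx <- findInterval(x, a)
    out <- ifelse(idx == 0, 0, cw[pmax(idx, 1)])
    pmin(pmax(out, 0), 1)
  }
  new_pdist("sbr", mean = mu, variance = s2, grid = a, pdf = f / width,
            cdf = cdf, fit = result,
            pdf_fun = function(u) {
              idx <- pmin(pmax(ceiling(u * result$M), 1L), result$M)
              val <- f[idx] / width
              val[u < 0 | u > 1] <- 0
              val
            })
}

#' Export the SBR iterate trajectory
#'
#' Long-format table (iteration, grid, weight) for sensitivity plots across
#' stopping points.
#'
#' @param result an `sbr_fit`.
#' @param path optional CSV path; if NULL the data frame is returned only.
#' @param iterations subset of iterations to export (default all).
#' @return The long-format data frame, invisibly if written to file.
#' @export
sbr_trajectory <- function(result, path = NULL, iterations = NULL) {
  stopifnot(inherits(result, "sbr_fit"))
  iterations <- iterations %||% 0:result$nu_N
  df <- do.call(rbind, lapply(iterations, function(v) {
    data.frame(iteration = v, grid = result$grid,
               weight = result$weights_by_iteration[v + 1L, ])
  }))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
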