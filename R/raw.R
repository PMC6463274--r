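#' Raw provider sample proportions
#'
#' `p_hat_i = y_i / n_i` for each provider. The spread of these values
#' overstates the spread of the latent probabilities: each carries binomial
#' sampling error with variance about `p_i (1 - p_i) / n_i`.
#'
#' @param counts a [provider_counts] object.
#' @return Numeric vector in `[0, 1]`, one entry per provider.
#' @export
raw_proportions <- function(counts) {
  stopifnot(inherits(counts, "provider_counts"))
  counts$y / counts$n
}

#' Population variance (1/N divisor)
#'
#' Mean squared deviation from the mean, i.e. the variance with divisor `N`
#' rather than `N - 1`. This is the estimand-matching definition used for
#' every variance reported by the package.
#'
#' @param values numeric vector, length >= 1.
#' @return Nonnegative scalar.
#' @export
population_variance <- function(values) {
  if (length(values) < 1L) stop("empty vector", call. = FALSE)
  mean((values - mean(values))^2)
}

#' Gaussian kernel density estimate
#'
#' Rule-of-thumb bandwidth `h = 0.9 min(sd, IQR/1.34) N^{-1/5}` (sd with the
#' N-1 divisor), evaluated on a 512-point grid spanning
#' `[min - 3h, max + 3h]` intersected with `range`. The grid may spill
#' outside `[0, 1]`; no renormalization or truncation is applied by default.
#' With `reflect = TRUE` the mass outside `[0, 1]` is folded back at the
#' boundaries instead.
#'
#' @param values numeric vector, length >= 2, nonconstant.
#' @param bandwidth optional positive bandwidth overriding the default rule.
#' @param range optional length-2 numeric limiting the evaluation window.
#' @param reflect fold kernel mass outside `[0, 1]` back at the boundaries.
#' @return A [pdist] object with `method = "raw"` semantics left to the
#'   caller: mean/variance are those of `values` (1/N divisor), the cdf is
#'   the empirical distribution function of `values`.
#' @export
kde <- function(values, bandwidth = NULL, range = NULL, reflect = FALSE) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (is.null(bandwidth)) {
    if (max(values) == min(values)) {
      stop(paste("values are constant; the default bandwidth is 0 --",
                 "supply an explicit bandwidth"), call. = FALSE)
    }
    bandwidth <- stats::bw.nrd0(values)
  }
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  from <- min(values) - 3 * bandwidth
  to <- max(values) + 3 * bandwidth
  if (!is.null(range)) {
    from <- max(from, range[1])
    to <- min(to, range[2])
  }
  grid <- seq(from, to, length.out = 512)
  # exact kernel sum (not the binned FFT approximation): the estimate is
  # defined as (Nh)^-1 sum phi((x - v_i)/h); evaluated pointwise for large
  # inputs to bound memory
  ksum <- function(x, v) {
    if (length(v) * length(x) <= 5e6) {
      colMeans(stats::dnorm(outer(v, x, `-`) / bandwidth)) / bandwidth
    } else {
      vapply(x, function(xi) {
        mean(stats::dnorm((xi - v) / bandwidth)) / bandwidth
      }, numeric(1))
    }
  }
  pdf <- ksum(grid, values)
  if (reflect) {
    pdf <- pdf + ksum(grid, -values) + ksum(grid, 2 - values)
    pdf[grid < 0 | grid > 1] <- 0
  }
  new_pdist(method = "raw",
            mean = mean(values),
            variance = population_variance(values),
            grid = grid, pdf = pdf,
            cdf = edf(values),
            support_points = values,
            bandwidth = bandwidth)
}

#' Empirical distribution function
#'
#' `F(x) = N^{-1} sum 1{v_i <= x}`, right-continuous.
#'
#' @param values numeric vector, length >= 1.
#' @return A vectorized step-function evaluator.
#' @export
edf <- function(values) {
  if (length(values) < 1L) stop("empty vector", call. = FALSE)
  v <- sort(values)
  N <- length(v)
  function(x) findInterval(x, v) / N
}

#' Raw-proportions estimate of the provider-probability distribution
#'
#' Bundles the sample proportions, their 1/N-divisor variance, EDF and
#' kernel density into a [pdist] with `method = "raw"`. This is both a
#' method under comparison (known to be over-dispersed) and shared plumbing:
#' moment-adjusted imputation reuses the same EDF/KDE machinery on adjusted
#' values.
#'
#' @param counts a [provider_counts] object.
#' @param ... passed to [kde()].
#' @return A [pdist] object.
#' @export
raw_estimate <- function(counts, ...) {
  p <- raw_proportions(counts)
  if (max(p) > min(p)) {
    out <- kde(p, ...)
  } else {
    # degenerate cohort: all proportions identical; represent as a narrow
    # spike so downstream metrics remain defined
    out <- kde(p, bandwidth = 1e-4, ...)
  }
  out$method <- "raw"
  out
}
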