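## Evaluation machinery: integrated squared distances between estimated and
## true distribution functions / densities, bias and MSE of the variance
## estimate, and the Monte Carlo study driver.

# evaluate an estimate's density at arbitrary points: analytic form when the
# estimate carries one, linear interpolation of the grid otherwise (0
# outside the grid)
pdist_pdf_at <- function(estimate, x) {
  if (!is.null(estimate$pdf_fun)) return(estimate$pdf_fun(x))
  stats::approx(estimate$grid, estimate$pdf, xout = x, yleft = 0,
                yright = 0, rule = 1)$y
}

#' Integrated squared CDF distance to the scenario truth
#'
#' `ED-CDF = int (F-hat(t) - F_p(t))^2 dt` on `[0, 1]` by composite Simpson
#' on a 2001-point grid (a fixed grid keeps the step discontinuities of
#' EDF-type estimates harmless).
#'
#' @param estimate a [pdist] (its `cdf` evaluator is used), or a function.
#' @param spec a [scenario_spec] supplying the true CDF.
#' @param n_grid odd number of Simpson points.
#' @return Nonnegative scalar.
#' @export
ed_cdf <- function(estimate, spec, n_grid = 2001) {
  Fhat <- if (is.function(estimate)) estimate else estimate$cdf
  t <- seq(0, 1, length.out = n_grid)
  simpson((Fhat(t) - true_cdf(spec, t))^2, t[2] - t[1])
}

#' Integrated squared density distance to the scenario truth
#'
#' Same fixed-grid Simpson quadrature applied to `(f-hat - f_p)^2`. The
#' integration window is the union of `[0, 1]` and the estimate's grid
#' range: where an estimate spills outside `[0, 1]` the true density is 0
#' there, and where the truth extends beyond the estimate's grid the
#' estimate contributes 0.
#'
#' @param estimate a [pdist] with density values.
#' @param spec a [scenario_spec].
#' @param n_grid odd number of Simpson points.
#' @return Nonnegative scalar.
#' @export
ed_pdf <- function(estimate, spec, n_grid = 2001) {
  lo <- min(0, min(estimate$grid))
  hi <- max(1, max(estimate$grid))
  t <- seq(lo, hi, length.out = n_grid)
  fhat <- pdist_pdf_at(estimate, t)
  inside <- t > 0 & t < 1
  fp <- numeric(n_grid)
  fp[inside] <- true_density(spec, t[inside])
  simpson((fhat - fp)^2, t[2] - t[1])
}

#' Bias and mean squared error of repeated estimates
#'
#' @param estimates numeric vector of per-replicate estimates (B >= 2).
#' @param truth the true value.
#' @return Named vector `c(bias, mse)`: `bias = mean - truth`,
#'   `mse = mean((estimate - truth)^2)`.
#' @export
bias_mse <- function(estimates, truth) {
  if (length(estimates) < 2L) stop("need B >= 2 estimates", call. = FALSE)
  c(bias = mean(estimates) - truth,
    mse = mean((estimates - truth)^2))
}

#' Monte Carlo comparison of estimators under a scenario
#'
#' For each of `B` replicates a cohort is simulated from the scenario (all
#' methods see the identical dataset - a paired design), each requested
#' method is fitted, and its variance estimate and integrated squared
#' distances against the exact truth are recorded. Per-replicate child
#' seeds are derived from `base_seed` by a counter scheme, so reports are
#' reproducible bit-for-bit. Individual fit failures are excluded from that
#' method's aggregate with a count; a method failing on more than 10% of
#' replicates is marked invalid.
#'
#' @param spec a [scenario_spec] (its own seed is ignored here).
#' @param methods character subset of
#'   `c("raw", "ghm", "ghm_eb", "mai", "sbr", "dp")`.
#' @param B number of replicates (>= 2).
#' @param base_seed integer seed for the whole study.
#' @param ed compute ED-CDF/ED-PDF (slightly costly; TRUE by default).
#' @param method_args named list of per-method argument lists passed to
#'   [fit_pdist()] (e.g. `list(mai = list(M = 2), dp = list(config = ...))`).
#' @return An object of class `mc_study`: `summary` data frame (one row per
#'   method: mean variance estimate, bias, ratio to true variance, MSE,
#'   mean ED-CDF, mean ED-PDF, percent MSE/ED reductions vs raw, failures,
#'   valid flag), `true_variance`, `B`, `base_seed`, per-replicate
#'   `variances` matrix.
#' @export
run_study <- function(spec, methods = c("raw", "mai"), B = 200,
                      base_seed = 1, ed = TRUE, method_args = list()) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  methods <- match.arg(methods,
                       c("raw", "ghm", "ghm_eb", "mai", "sbr", "dp"),
                       several.ok = TRUE)
  tv <- true_variance(spec)
  nm <- length(methods)
  vars <- matrix(NA_real_, nrow = B, ncol = nm,
                 dimnames = list(NULL, methods))
  edc <- edp <- matrix(NA_real_, nrow = B, ncol = nm,
                       dimnames = list(NULL, methods))
  # ghm and ghm_eb share one model fit per replicate
  share_ghm <- all(c("ghm", "ghm_eb") %in% methods)
  for (b in seq_len(B)) {
    sd_b <- child_seed(base_seed, b)
    spec_b <- spec
    spec_b$seed <- sd_b
    pc <- simulate_cohort(spec_b)
    ghm_fit_b <- NULL
    if (share_ghm) {
      ghm_fit_b <- tryCatch(fit_ghm(pc), error = function(e) NULL)
    }
    for (j in seq_len(nm)) {
      mth <- methods[j]
      # warnings (e.g. MAI collapse detection) do not invalidate a fit
      est <- suppressWarnings(tryCatch({
        if (!is.null(ghm_fit_b) && mth == "ghm") {
          ghm_density(ghm_fit_b)
        } else if (!is.null(ghm_fit_b) && mth == "ghm_eb") {
          eb_predictions(ghm_fit_b, pc)
        } else {
          do.call(fit_pdist,
                  c(list(counts = pc, method = mth),
                    method_args[[mth]] %||% list()))
        }
      }, error = function(e) NULL))
      if (is.null(est)) next
      vars[b, j] <- est$variance
      if (ed) {
        edc[b, j] <- ed_cdf(est, spec)
        edp[b, j] <- ed_pdf(est, spec)
      }
    }
  }
  n_fail <- colSums(is.na(vars))
  mv <- colMeans(vars, na.rm = TRUE)
  mse <- colMeans((vars - tv)^2, na.rm = TRUE)
  medc <- colMeans(edc, na.rm = TRUE)
  medp <- colMeans(edp, na.rm = TRUE)
  raw_ref <- function(x) {
    if (!"raw" %in% methods) return(rep(NA_real_, nm))
    100 * (1 - x / x[["raw"]])
  }
  summary <- data.frame(
    method = methods,
    mean_variance = mv,
    bias = mv - tv,
    ratio = mv / tv,
    mse = mse,
    mean_ed_cdf = if (ed) medc else NA_real_,
    mean_ed_pdf = if (ed) medp else NA_real_,
    pct_mse_reduction = raw_ref(mse),
    pct_ed_cdf_reduction = if (ed) raw_ref(medc) else NA_real_,
    n_fail = n_fail,
    valid = n_fail <= 0.1 * B,
    row.names = NULL)
  structure(list(summary = summary, true_variance = tv, B = B,
                 base_seed = base_seed, spec = spec,
                 variances = vars,
                 ed_cdf = if (ed) edc else NULL,
                 ed_pdf = if (ed) edp else NULL),
            class = "mc_study")
}

#' @export
print.mc_study <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Monte Carlo study: %s law, sigma_b2 %g, N %d, B %d (true variance %.6f)\n",
    x$spec$law, x$spec$sigma_b2, x$spec$N, x$B, x$true_variance))
  df <- x$summary
  df[-1] <- lapply(df[-1], function(col) {
    if (is.numeric(col)) signif(col, digits) else col
  })
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tidy per-method metric table from a study
#'
#' @param x an `mc_study`.
#' @param path optional CSV path.
#' @return Data frame with columns scenario, method, metric, value.
#' @export
study_tidy <- function(x, path = NULL) {
  stopifnot(inherits(x, "mc_study"))
  scen <- sprintf("%s_s%g_N%d", x$spec$law, x$spec$sigma_b2, x$spec$N)
  long <- do.call(rbind, lapply(seq_len(nrow(x$summary)), function(i) {
    row <- x$summary[i, ]
    metrics <- c("mean_variance", "bias", "ratio", "mse", "mean_ed_cdf",
                 "mean_ed_pdf", "pct_mse_reduction", "n_fail")
    data.frame(scenario = scen, method = row$method, metric = metrics,
               value = as.numeric(row[metrics]))
  }))
  if (!is.null(path)) {
    utils::write.csv(long, path, row.names = FALSE)
    return(invisible(long))
  }
  long
}
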