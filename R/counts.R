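#' Provider-level binomial counts
#'
#' Container for the observed two-stage hierarchy: for each of `N` providers
#' (hospitals, clinics, physicians) an event count `y` out of `n` patients.
#' The latent provider probability `p_i` is never observed; every estimator in
#' the package starts from this object.
#'
#' @param provider_id vector of unique provider labels (coerced to character).
#' @param y integer vector of event counts, `0 <= y_i <= n_i`.
#' @param n integer vector of patient counts, `n_i >= 1`.
#' @return An object of class `provider_counts`: a data frame with columns
#'   `provider_id`, `y`, `n` and attribute `N` (number of providers).
#' @examples
#' pc <- provider_counts(c("A", "B"), y = c(10, 5), n = c(40, 20))
#' raw_proportions(pc)
#' @export
provider_counts <- function(provider_id, y, n) {
  provider_id <- as.character(provider_id)
  if (anyDuplicated(provider_id)) {
    stop("duplicate provider_id values", call. = FALSE)
  }
  if (length(y) != length(provider_id) || length(n) != length(provider_id)) {
    stop("provider_id, y and n must have equal length", call. = FALSE)
  }
  if (length(y) < 1L) stop("at least one provider required", call. = FALSE)
  if (any(is.na(y)) || any(is.na(n))) {
    stop("missing values in counts", call. = FALSE)
  }
  if (any(y != round(y)) || any(n != round(n))) {
    stop("counts must be integers", call. = FALSE)
  }
  y <- as.integer(round(y))
  n <- as.integer(round(n))
  if (any(n < 1L)) stop("n must be >= 1", call. = FALSE)
  if (any(y < 0L)) stop("y must be >= 0", call. = FALSE)
  if (any(y > n)) stop("y exceeds n", call. = FALSE)
  out <- data.frame(provider_id = provider_id, y = y, n = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("provider_counts", "data.frame")
  out
}

#' @export
print.provider_counts <- function(x, ...) {
  p <- x$y / x$n
  cat(sprintf("provider_counts: %d providers, %d patients\n",
              nrow(x), sum(x$n)))
  cat(sprintf("  site size: median %g (IQR %g-%g)\n",
              stats::median(x$n),
              stats::quantile(x$n, 0.25), stats::quantile(x$n, 0.75)))
  cat(sprintf("  raw proportion: mean %.4f, range %.4f-%.4f\n",
              mean(p), min(p), max(p)))
  invisible(x)
}

#' Read provider counts from a delimited text file
#'
#' Accepts either a provider-level table with header `provider_id,y,n` (one
#' row per provider) or a patient-level table with header
#' `provider_id,outcome` (one row per patient, outcome 0/1), which is
#' aggregated by provider on ingestion. The delimiter is inferred from the
#' extension (`.tsv`/`.txt` = tab), comma otherwise.
#'
#' @param path file path.
#' @return A [provider_counts] object.
#' @export
read_counts <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (all(c("provider_id", "y", "n") %in% names(df))) {
    return(provider_counts(df$provider_id, df$y, df$n))
  }
  if (all(c("provider_id", "outcome") %in% names(df))) {
    if (!all(df$outcome %in% c(0, 1))) {
      stop("patient-level outcome must be 0/1", call. = FALSE)
    }
    agg <- stats::aggregate(df$outcome, by = list(provider_id = df$provider_id),
                            FUN = function(v) c(y = sum(v), n = length(v)))
    return(provider_counts(agg$provider_id, agg$x[, "y"], agg$x[, "n"]))
  }
  stop("missing columns: need provider_id,y,n or provider_id,outcome",
       call. = FALSE)
}

#' Write provider counts to a delimited text file
#'
#' Round-trips the `provider_id,y,n` schema read by [read_counts()].
#'
#' @param counts a [provider_counts] object.
#' @param path output file path; `.tsv`/`.txt` write tab-delimited.
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "provider_counts"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(counts)[, c("provider_id", "y", "n")],
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Exclude providers with very small patient counts
#'
#' Small sites carry so much binomial sampling error that the provider-level
#' density becomes unidentifiable without strong parametric assumptions.
#' Convention in the applied literature is to exclude `n_i < 25`; with the
#' adjustment estimators in this package the rule can be relaxed, and a
#' minimum of `n_i > 10` together with a median site size above 20 is
#' sufficient in practice. The default `min_n = 10` reflects the relaxed rule;
#' set `min_n = 25` to mimic the naive convention.
#'
#' @param counts a [provider_counts] object.
#' @param min_n providers with `n_i < min_n` are dropped.
#' @param min_median_n optional: warn if the median retained site size falls
#'   below this (validation only; nothing further is dropped).
#' @param quiet suppress the exclusion log line.
#' @return The filtered [provider_counts].
#' @export
filter_small_sites <- function(counts, min_n = 10, min_median_n = NULL,
                               quiet = FALSE) {
  stopifnot(inherits(counts, "provider_counts"))
  if (min_n < 1) stop("min_n must be >= 1", call. = FALSE)
  keep <- counts$n >= min_n
  if (!any(keep)) stop("no providers remain after filtering", call. = FALSE)
  out <- provider_counts(counts$provider_id[keep], counts$y[keep],
                         counts$n[keep])
  if (!quiet && !all(keep)) {
    message(sprintf(
      "filter_small_sites: excluded %d/%d providers (%.1f%%) and %.2f%% of patients (n < %g)",
      sum(!keep), nrow(counts), 100 * mean(!keep),
      100 * sum(counts$n[!keep]) / sum(counts$n), min_n))
  }
  if (!is.null(min_median_n) && stats::median(out$n) < min_median_n) {
    warning(sprintf("median retained site size %g is below %g",
                    stats::median(out$n), min_median_n), call. = FALSE)
  }
  out
}
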