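## Moment-adjusted imputation (MAI).
##
## The observed proportion is treated as W_i = X_i + U_i with X_i the latent
## provider probability and U_i approximately Normal(0, sigma_ui^2),
## sigma_ui^2 = p_i (1 - p_i) / n_i. MAI replaces W by the minimally
## displaced values X-hat whose first M sample moments unbiasedly estimate
## the moments of X: minimize sum (W_i - X_i)^2 subject to
## N^-1 sum X_i^r = m-hat_r, r = 1..M, solved by Newton-Raphson on the
## stationarity system of the Lagrangian.

#' Binomial measurement-error variances of the raw proportions
#'
#' Plug-in error variance `sigma_ui^2 = p(1-p)/n` per provider, with the
#' continuity-corrected proportion `(y + 0.5)/(n + 1)` substituted when
#' `y = 0` or `y = n` so the variance is never exactly zero (the raw plug-in
#' would silently treat boundary sites as noiseless).
#'
#' @param counts a [provider_counts] object.
#' @return Nonnegative numeric vector, one entry per provider.
#' @export
error_variances <- function(counts) {
  stopifnot(inherits(counts, "provider_counts"))
  p <- counts$y / counts$n
  boundary <- counts$y == 0L | counts$y == counts$n
  p[boundary] <- (counts$y[boundary] + 0.5) / (counts$n[boundary] + 1)
  p * (1 - p) / counts$n
}

#' Unbiased moment estimates under additive normal error
#'
#' Given `W_i = X_i + U_i` with `U_i ~ Normal(0, sigma_ui^2)`, the raw
#' sample moments of `W` are biased for the moments of `X`; the corrected
#' summands
#' \deqn{m_1 = \bar W,\quad m_2 = \overline{W^2 - \sigma^2_u},\quad
#'       m_3 = \overline{W^3 - 3W\sigma^2_u},\quad
#'       m_4 = \overline{W^4 - 6W^2\sigma^2_u + 3\sigma^4_u}}
#' are exactly unbiased (Hermite-polynomial deconvolution of the normal
#' error).
#'
#' @param W observed values.
#' @param sigma_u2 per-observation error variances (same length as `W`).
#' @param M number of moments, 1 to 4.
#' @return Numeric vector `m[1..M]`.
#' @export
unbiased_moments <- function(W, sigma_u2, M) {
  stopifnot(length(W) == length(sigma_u2))
  if (!M %in% 1:4) stop("M must be in 1..4", call. = FALSE)
  m <- numeric(M)
  m[1] <- mean(W)
  if (M >= 2) m[2] <- mean(W^2 - sigma_u2)
  if (M >= 3) m[3] <- mean(W^3 - 3 * W * sigma_u2)
  if (M >= 4) m[4] <- mean(W^4 - 6 * W^2 * sigma_u2 + 3 * sigma_u2^2)
  m
}

# Newton-Raphson on the stationarity system of the Lagrangian:
#   F_i: (X_i - W_i) + sum_r lambda_r X_i^(r-1) = 0,  i = 1..N
#   G_r: N^-1 sum_i X_i^r - m_r = 0,                  r = 1..M
# The (N+M) x (N+M) Jacobian has arrow structure (diagonal X-block, M
# border rows/columns), solved via its Schur complement in O(N M^2).
mai_newton <- function(W, m, M, X = W, lambda = numeric(M),
                       max_iter = 200, tol = 1e-10) {
  N <- length(W)
  residuals <- function(X, lambda) {
    XP <- cbind(1, outer(X, seq_len(M), `^`))   # cols: X^0 .. X^M
    Fi <- (X - W) + drop(XP[, 1:M, drop = FALSE] %*% lambda)
    Gr <- colMeans(XP[, 2:(M + 1), drop = FALSE]) - m
    list(Fi = Fi, Gr = Gr, XP = XP)
  }
  res <- residuals(X, lambda)
  maxres <- max(abs(c(res$Fi, res$Gr)))
  iter <- 0L
  while (maxres > tol && iter < max_iter) {
    iter <- iter + 1L
    XP <- res$XP
    # dF_i/dX_i = 1 + sum_{r>=2} lambda_r (r-1) X_i^(r-2)
    d <- rep(1, N)
    if (M >= 2) {
      for (r in 2:M) d <- d + lambda[r] * (r - 1) * XP[, r - 1]
    }
    B <- XP[, 1:M, drop = FALSE]                       # dF_i/dlambda_r
    C <- sweep(XP[, 1:M, drop = FALSE], 2, seq_len(M), `*`) / N
    # C[i, r] = r X_i^(r-1) / N; dG_r/dX_i = t(C)
    dinv <- 1 / d
    S <- -t(C * dinv) %*% B                            # M x M Schur complement
    rhs <- -res$Gr + drop(t(C * dinv) %*% res$Fi)
    dl <- tryCatch(solve(S, rhs), error = function(e) NULL)
    if (is.null(dl) || any(!is.finite(dl))) return(NULL)
    dX <- -dinv * (res$Fi + drop(B %*% dl))
    # step-halving line search on the max residual
    step <- 1
    repeat {
      Xn <- X + step * dX
      ln <- lambda + step * dl
      resn <- residuals(Xn, ln)
      mn <- max(abs(c(resn$Fi, resn$Gr)))
      if (is.finite(mn) && (mn < maxres || step < 1e-6)) break
      step <- step / 2
    }
    if (!is.finite(mn) || mn >= maxres) break
    X <- Xn
    lambda <- ln
    res <- resn
    maxres <- mn
  }
  if (maxres > tol) return(NULL)
  list(X = X, lambda = lambda, iterations = iter, max_residual = maxres)
}

#' Moment-adjusted values by constrained least displacement
#'
#' Solves `min sum (W_i - X_i)^2` subject to the first `M` sample moments of
#' `X` equaling the unbiased target moments, by Newton-Raphson on the joint
#' stationarity system with step-halving and jittered restarts. The solve is
#' performed on internally standardized values (the problem is
#' affine-equivariant) for numerical conditioning, and mapped back.
#'
#' @param W observed values (raw proportions).
#' @param sigma_u2 per-observation error variances.
#' @param M number of moments to match (2 or 4 recommended; 4 default
#'   captures skewness and kurtosis of non-normal laws).
#' @param fallback when the third/fourth target moments are unattainable
#'   (see Details) or the Newton iteration fails, fall back to matching two
#'   moments with a warning instead of erroring.
#'
#' @details At very low signal-to-noise ratios the deconvolved third and
#' fourth moment estimates can violate the Cauchy-Schwarz/Hankel
#' constraints every genuine distribution satisfies (e.g.
#' `m3^2 <= m2 m4`); no set of adjusted values can then match them and the
#' Newton system has no solution. Such targets are detected up front (a
#' non-positive-definite Hankel moment matrix) and, with
#' `fallback = TRUE` (default), the adjustment drops to the always-feasible
#' two-moment problem, which keeps the mean and variance unbiased; the
#' returned `M` records the number actually matched. The feasible quartic
#' solve is warm-started at the affine two-moment solution and continued
#' along a homotopy of the target moments.
#'
#' @return An object of class `mai_fit`: list with `adjusted`,
#'   `multipliers` (Lagrange multipliers, standardized scale),
#'   `target_moments`, `M` (moments actually matched), `M_requested`,
#'   `error_variances`, `iterations`, `max_constraint_violation`,
#'   `frac_outside_unit`.
#' @export
mai_adjust <- function(W, sigma_u2, M = 4, fallback = TRUE) {
  N <- length(W)
  if (!M %in% 1:4) stop("M must be in 1..4", call. = FALSE)
  if (N <= M) stop("need more observations than moments", call. = FALSE)
  M_req <- M
  m_raw <- unbiased_moments(W, sigma_u2, max(M, 2))
  if (m_raw[2] - m_raw[1]^2 <= 0) {
    stop("noise exceeds estimated signal: corrected variance is not positive",
         call. = FALSE)
  }
  if (all(sigma_u2 == 0)) {
    return(structure(list(adjusted = W, multipliers = numeric(M),
                          target_moments = m_raw[seq_len(M)], M = M,
                          M_requested = M_req,
                          error_variances = sigma_u2, iterations = 0L,
                          max_constraint_violation = 0,
                          frac_outside_unit = mean(W < 0 | W > 1)),
                     class = "mai_fit"))
  }
  # standardize: W' = (W - c)/s, error variance scales by 1/s^2
  c0 <- mean(W)
  s0 <- stats::sd(W)
  if (s0 <= 0) s0 <- 1
  Ws <- (W - c0) / s0
  ms <- unbiased_moments(Ws, sigma_u2 / s0^2, M)
  if (M >= 3 && !moments_feasible(ms)) {
    if (!fallback) {
      stop(paste("target moments are unattainable (Hankel constraint",
                 "violated at this noise level); no adjusted values can",
                 "match them"), call. = FALSE)
    }
    warning(sprintf(
      "third/fourth target moments unattainable at this noise level; matching 2 moments instead of %d",
      M), call. = FALSE)
    M <- 2L
    ms <- ms[1:2]
  }
  sol <- mai_solve(Ws, ms, M)
  if (is.null(sol) && fallback && M > 2L) {
    warning(sprintf(
      "Newton-Raphson failed for %d moments; matching 2 moments instead", M),
      call. = FALSE)
    M <- 2L
    ms <- ms[1:2]
    sol <- mai_solve(Ws, ms, M)
  }
  if (is.null(sol)) {
    stop("MAI Newton-Raphson failed to converge after restarts",
         call. = FALSE)
  }
  X <- c0 + s0 * sol$X
  m_orig <- unbiased_moments(W, sigma_u2, M)
  viol <- max(abs(vapply(seq_len(M), function(r) mean(X^r) - m_orig[r],
                         numeric(1))))
  fit <- structure(list(adjusted = X,
                        multipliers = sol$lambda,
                        target_moments = m_orig, M = M,
                        M_requested = M_req,
                        error_variances = sigma_u2,
                        iterations = sol$iterations,
                        max_constraint_violation = viol,
                        frac_outside_unit = mean(X < 0 | X > 1)),
                   class = "mai_fit")
  # rare small-n pathology: distinct observed values collapsing onto a few
  # atoms (ties already present in W map to tied X by construction and are
  # not a collapse)
  cl <- collapsed_fraction(X[!duplicated(W)])
  if (cl > 0.2) {
    warning(sprintf(
      "%.0f%% of adjusted values collapse into near-identical clusters; the implied density may show spurious discrete mass",
      100 * cl), call. = FALSE)
  }
  fit
}

# Necessary feasibility of raw moments (m1..m4): the Hankel moment matrix
# [[1, m1, m2], [m1, m2, m3], [m2, m3, m4]] must be positive semidefinite
# for any distribution. A small positive margin is required because a
# boundary target (degenerate support) is not reachable by Newton either.
moments_feasible <- function(m, margin = 1e-9) {
  M <- length(m)
  if (M < 3) return(m[2] - m[1]^2 > margin)
  m3 <- m[3]
  m4 <- if (M >= 4) m[4] else NA_real_
  H <- if (M >= 4) {
    matrix(c(1, m[1], m[2], m[1], m[2], m3, m[2], m3, m4), 3, 3)
  } else {
    matrix(c(1, m[1], m[1], m[2]), 2, 2)
  }
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  all(ev > margin)
}

# Affine two-moment solution (exact) and its Lagrange multipliers, used both
# as the M = 2 solution and as a warm start for higher M.
mai_affine <- function(W, m) {
  sW2 <- mean((W - mean(W))^2)
  b <- sqrt((m[2] - m[1]^2) / sW2)
  X <- m[1] + b * (W - mean(W))
  list(X = X, lambda = c(mean(W) - m[1] / b, 1 / b - 1),
       iterations = 0L, max_residual = 0)
}

# Full solve strategy: exact affine for M <= 2; otherwise Newton from the
# affine warm start, then a 4-step homotopy from the affine solution's own
# moments to the targets, then jittered restarts.
mai_solve <- function(W, m, M) {
  if (M == 1L) {
    X <- W - mean(W) + m[1]
    return(list(X = X, lambda = mean(W) - m[1], iterations = 0L,
                max_residual = 0))
  }
  aff <- mai_affine(W, m[1:2])
  if (M == 2L) {
    # polish to clear rounding in b
    sol <- mai_newton(W, m, M, X = aff$X, lambda = aff$lambda)
    return(sol %||% aff)
  }
  lam0 <- c(aff$lambda, numeric(M - 2L))
  sol <- mai_newton(W, m, M, X = aff$X, lambda = lam0)
  if (!is.null(sol)) return(sol)
  # homotopy on the targets (moment space is convex)
  m_aff <- vapply(seq_len(M), function(r) mean(aff$X^r), numeric(1))
  X <- aff$X
  lambda <- lam0
  for (t in c(0.25, 0.5, 0.75, 1)) {
    mt <- (1 - t) * m_aff + t * m
    st <- mai_newton(W, mt, M, X = X, lambda = lambda)
    if (is.null(st)) break
    X <- st$X
    lambda <- st$lambda
    if (t == 1) return(st)
  }
  # jittered restarts from perturbed warm starts
  for (tries in 1:5) {
    Xj <- aff$X + stats::rnorm(length(W), 0, 0.05 * tries)
    sj <- mai_newton(W, m, M, X = Xj, lambda = lam0)
    if (!is.null(sj)) return(sj)
  }
  NULL
}

collapsed_fraction <- function(X, eps = 1e-6) {
  Xs <- sort(X)
  in_cluster <- c(FALSE, diff(Xs) < eps)
  mean(in_cluster | c(in_cluster[-1], FALSE))
}

#' @export
print.mai_fit <- function(x, ...) {
  cat(sprintf(
    "MAI adjustment: %d values, %d moments matched in %d Newton iterations\n",
    length(x$adjusted), x$M, x$iterations))
  cat(sprintf("  max constraint violation %.2e; %.1f%% of values outside [0,1]\n",
              x$max_constraint_violation, 100 * x$frac_outside_unit))
  invisible(x)
}

#' Moment-adjusted imputation estimate of the provider distribution
#'
#' Composes [raw_proportions()], [error_variances()], [unbiased_moments()]
#' and [mai_adjust()], then summarizes the adjusted values with the
#' 1/N-divisor variance, EDF and kernel density, exactly as for raw
#' proportions. Matching four moments (default) gives unbiased mean,
#' variance, skewness and kurtosis, capturing non-normal shapes; adjusted
#' values may fall slightly outside `[0, 1]` and are not clipped (clipping
#' would bias the matched moments).
#'
#' @param counts a [provider_counts] object.
#' @param M number of moments to match (default 4).
#' @param ... passed to [kde()].
#' @return A [pdist] with `method = "mai"` and the `mai_fit` in `$fit`.
#' @export
mai_estimate <- function(counts, M = 4, ...) {
  W <- raw_proportions(counts)
  s2 <- error_variances(counts)
  fit <- mai_adjust(W, s2, M = M)
  X <- fit$adjusted
  if (max(X) - min(X) > 1e-10) {
    out <- kde(X, ...)
  } else {
    out <- kde(X, bandwidth = 1e-4, ...)
  }
  out$method <- "mai"
  out$fit <- fit
  out
}
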