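## Internal numerical helpers shared across estimators.

# Cached Gauss-Hermite rules (physicists' weight exp(-x^2)).
.gh_cache <- new.env(parent = emptyenv())

gh_rule <- function(n) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]])) {
    .gh_cache[[key]] <- pracma::gaussHermite(n)
  }
  .gh_cache[[key]]
}

# E[g(Z)] for Z ~ N(0,1): sum w_k g(sqrt(2) x_k) / sqrt(pi)
gauss_hermite_expect <- function(g, n = 201) {
  r <- gh_rule(n)
  sum(r$w * g(sqrt(2) * r$x)) / sqrt(pi)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

expit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

# Composite Simpson on an odd-length equally spaced grid.
simpson <- function(y, h) {
  n <- length(y)
  stopifnot(n >= 3L, n %% 2L == 1L)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1
  w[n] <- 1
  h / 3 * sum(w * y)
}

# Counter-based child seeds: method comparisons within a replicate share the
# same dataset, and the whole stream is reproducible from one base seed.
child_seed <- function(base_seed, b) {
  as.integer((as.numeric(base_seed) + 999983 * as.numeric(b)) %% 2147483647)
}

# Run code under a local RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
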