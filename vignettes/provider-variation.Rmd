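---
title: "Estimating between-provider variation in binomial outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating between-provider variation in binomial outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Quality-improvement studies ask how much a dichotomous treatment or outcome
truly varies across providers (hospitals, clinics, physicians). The data are
hierarchical: provider $i$ contributes $y_i$ events among $n_i$ patients,

$$Y_i \mid p_i \sim \mathrm{Binomial}(n_i, p_i), \qquad p_i \sim F_p,$$

and the estimand is the distribution $F_p$ of the latent provider
probabilities — above all its variance
$\sigma_p^2 = \int (u - \mu_p)^2 f_p(u)\,du$ and its density $f_p$, which is
what investigators plot. The naive histogram of raw proportions
$\hat p_i = y_i / n_i$ is *over-dispersed*: each $\hat p_i$ carries binomial
sampling error of variance roughly $p_i(1 - p_i)/n_i$, which at typical site
sizes can dwarf the real signal. Conversely, the spread of empirical-Bayes
shrinkage predictions from a hierarchical model *understates* $\sigma_p^2$.
This package implements both naive references and four adjustment
estimators, together with a simulation engine and metrics for comparing
them.

```{r}
library(providervar)
spec <- scenario_spec("normal", sigma_b2 = 0.05, N = 300,
                      size_profile = "fixed30", seed = 1)
pc <- simulate_cohort(spec)
fit_pdist(pc, method = "mai")
```

## The estimators

**Raw proportions** (`raw_estimate()`). $\hat p_i = y_i/n_i$, summarized by
the $1/N$-divisor variance
$\hat\sigma^2_{\hat p} = N^{-1}\sum_i(\hat p_i - \bar{\hat p})^2$, the
empirical distribution function, and a Gaussian kernel density estimate.
The $1/N$ divisor (not $N-1$) is used for every variance the package
reports, matching the estimand's definition; at the provider counts
involved the difference is below one percent. The KDE uses the
rule-of-thumb bandwidth $h = 0.9\,\min(\mathrm{sd}, \mathrm{IQR}/1.34)\,
N^{-1/5}$ (sd with the $N-1$ divisor) and evaluates the exact kernel sum on
a 512-point grid spanning $[\min - 3h, \max + 3h]$; the grid may spill
slightly outside $[0,1]$ and is deliberately neither truncated nor
renormalized, because truncation would bias the moments the estimators work
hard to get right (a reflect-at-boundary mode is available but off by
default).

**Gaussian hierarchical model** (`fit_ghm()`). The random-intercept
logistic model $\mathrm{logit}(p_i) = \beta_0 + b_i$,
$b_i \sim N(0, \sigma_b^2)$, fitted by maximizing the marginal likelihood
with the random effect integrated out by adaptive Gauss–Hermite quadrature
(25 nodes by default, centered at each provider's conditional mode and
scaled by the curvature there; naive quadrature is inaccurate at small
$n_i$). Optimization is a derivative-free simplex over
$(\beta_0, \log\sigma_b)$ from a method-of-moments start with one jittered
restart; a boundary solution $\hat\sigma_b \approx 0$ is a legitimate
answer, not an error. Providers with identical $(y_i, n_i)$ are collapsed
before quadrature, which makes the fit fast at fixed site sizes. On the
probability scale the fitted law is the closed-form logit-normal

$$\hat f_p(u) = \frac{\phi\{(\mathrm{logit}(u) - \hat\beta_0)/
\hat\sigma_b\}}{\hat\sigma_b\, u (1-u)},$$

used directly rather than by simulating and smoothing draws — the
distribution is deterministic given the parameter estimates, so there is no
reason to re-inject Monte Carlo noise. Its variance
$\mathrm{Var}[\mathrm{expit}(\hat\beta_0 + \hat\sigma_b Z)]$ is computed by
Gauss–Hermite quadrature with at least 201 nodes, doubled until stable to
$10^{-8}$ relative.

**Empirical-Bayes predictions** (`eb_predictions()`). Posterior means
$E[\mathrm{expit}(\beta_0 + b)\mid y_i]$ under the fitted Gaussian prior,
by the same adaptive quadrature. The posterior *mean* is the default
because it is a well-defined quadrature contract; the posterior mode is
available via `type = "mode"` since mixed-model software conventions
differ. These predictions are included purely as the over-shrunk
comparator: their spread understates $\sigma_p^2$, and the package's tests
assert that direction rather than treat it as a defect.

**Dirichlet-process beta-binomial mixture** (`dp_fit()`). A DP prior with
concentration $\alpha$ and conjugate $\mathrm{Beta}(a_1, b_1)$ base
(default uniform) over the provider probabilities. Conjugacy allows the
cluster parameters to be integrated out, so the sampler is a collapsed
Polya-urn Gibbs over partitions — exact in distribution and faster-mixing
than samplers that carry cluster parameters. With a Gamma hyper-prior on
$\alpha$ (rate parameterization, mean $a_0/b_0$ — the interoperability-
critical convention: the `dp2` preset with shape 10 and rate 0.10 implies
mean 100 and a prior 95% cluster interval of roughly 53–83 providers out of
100, which the scale parameterization would not reproduce), $\alpha$ is
refreshed per sweep by the standard beta-augmentation conditional. The
posterior density is Rao-Blackwellized: each retained draw contributes an
explicit mixture of Beta densities, and the posterior variance is computed
from that averaged density, matching the definition of the estimand as an
integral against $f_{p\mid Y}$ rather than a variance of atoms.
`prior_cluster_distribution()` simulates the implied prior number of
clusters (the new-table indicators of the Chinese-restaurant process are
independent Bernoullis, so the cluster count is sampled exactly and
cheaply) and is the tool for calibrating hyper-priors before fitting.
MCMC defaults (`n_iter = 5000`, `burn_in = 1000`, `thin = 4`) are sized for
desk runs at up to a few hundred providers; all are configurable.

**Smoothing by roughening** (`sbr_fit()`). Nonparametric empirical Bayes:
discretize the prior on $M = 500$ mass points (midpoints of equal-width
bins of $[0,1]$ — the placement is this package's choice), start uniform,
and apply exactly $\nu_N$ EM updates

$$f_{\nu+1}(a_m) = \frac{1}{N}\sum_{i=1}^N
\frac{f(Y_i\mid a_m) f_\nu(a_m)}{\sum_{m'} f(Y_i\mid a_{m'})
f_\nu(a_{m'})}.$$

Run to convergence this is the nonparametric MLE, which is discrete and
under-dispersed; stopping early retains smoothness. The default
$\nu_N = 50$ works well across the scenarios studied here, but no stopping
rule is universally good — published guidance for moderate samples spans
$N/3$ to $2N$ — so every iterate is retained and `sbr_trajectory()` exports
them for sensitivity plots. The $N \times M$ likelihood matrix is computed
once in log space and reused; each run asserts the EM ascent of the
marginal likelihood.

**Moment-adjusted imputation** (`mai_adjust()`, `mai_estimate()`). The
proposed adjustment views $\hat p_i$ as a noisy measurement
$W_i = X_i + U_i$ of the latent $X_i = p_i$, with
$U_i \sim N(0, \sigma^2_{ui})$ and plug-in
$\hat\sigma^2_{ui} = \hat p_i (1 - \hat p_i)/n_i$ treated as known. Where
$y_i \in \{0, n_i\}$ the plug-in would be exactly zero — silently treating
the noisiest sites as noiseless — so the variance plug-in (only) uses the
continuity-corrected $(y_i + 0.5)/(n_i + 1)$; $W_i$ itself stays $y_i/n_i$.
Unbiased moment estimates under normal additive error are

$$\hat m_1 = \overline{W},\quad
\hat m_2 = \overline{W^2 - \sigma^2_u},\quad
\hat m_3 = \overline{W^3 - 3W\sigma^2_u},\quad
\hat m_4 = \overline{W^4 - 6W^2\sigma^2_u + 3\sigma^4_u},$$

and the adjusted values solve $\min \sum_i (W_i - X_i)^2$ subject to
$N^{-1}\sum_i X_i^r = \hat m_r$, $r = 1..M$, via Newton–Raphson on the
Lagrangian stationarity system. The $(N+M)\times(N+M)$ Jacobian has arrow
structure (diagonal plus $M$ border rows), so each iteration is
$O(NM^2)$ via the Schur complement; the solve is performed on standardized
values (the problem is affine-equivariant) and is warm-started at the
exact affine two-moment solution, with a homotopy over the target moments
and jittered restarts behind it. Convergence demands a maximum residual of
$10^{-10}$; matched moments are verified to $10^{-8}$ on the original
scale. Adjusted values may fall slightly outside $[0,1]$ and are *not*
clipped (clipping would break the matched moments); the fraction outside
is recorded.

### When four moments cannot be matched

Matching $M = 4$ moments is the default, capturing skewness and kurtosis
of non-normal provider distributions. But the corrected third and fourth
moments are noisy, and at low signal-to-noise ratios (e.g.
$\sigma_b^2 = 0.05$ with $n_i = 30$, where the sampling noise variance is
about 3.5 times the signal variance) the estimated vector
$(\hat m_1, ..., \hat m_4)$ frequently violates the Hankel/Cauchy–Schwarz
constraints that the moments of *any* real distribution satisfy
(e.g. $\hat m_3^2 \le \hat m_2 \hat m_4$ for centered values). No set of
adjusted values can match such targets, and no solver can conjure one.
`mai_adjust()` therefore tests feasibility up front
(positive-definiteness of the Hankel moment matrix) and, when the quartic
target is unattainable — or the Newton iteration fails anyway — falls back
to the always-feasible two-moment match, with a warning and with the
result's `M` recording what was actually matched. The mean and variance,
which carry the headline comparisons, remain unbiased under the fallback;
`fallback = FALSE` restores a hard error. If even the corrected variance
$\hat m_2 - \hat m_1^2$ is nonpositive, the noise has swamped the signal
entirely and the adjustment refuses with a named error rather than
fabricate a distribution.

A second, rarer pathology at very small $n_i$ is adjusted values
collapsing onto a few discrete atoms; the fit warns when more than 20% of
*distinct* observed values merge to within $10^{-6}$ (ties already present
in the raw proportions are not counted — at fixed $n_i$, equal $y_i$ must
map to equal adjusted values).

## The simulation engine

`scenario_spec()` fixes a generative truth: logit-scale effects
$b_i$ with variance $\sigma_b^2$ from one of three laws — normal;
standardized $\chi^2_1$, i.e. $\sigma_b (V - 1)/\sqrt 2$ with
$V \sim \chi^2_1$ (skewness $2\sqrt 2$, a one-sided support bound at
$b = -\sigma_b/\sqrt 2$ where the density is 0 rather than an error); and
a bimodal equal mixture $\tfrac12 N(-\delta, \tau^2) +
\tfrac12 N(\delta, \tau^2)$ with $\delta^2 + \tau^2 = \sigma_b^2$ and
$\delta/\tau = 2$, a separation chosen to give two clearly resolved modes
while keeping the variance exactly $\sigma_b^2$. The intercept defaults to
$\beta_0 = \mathrm{logit}(0.25)$, representative of the early-follow-up
rates (roughly 20–33%) that motivate the problem; both choices are
configurable and results that depend on them are treated as directional
properties, not point targets.

Site sizes come either fixed (20 or 30) or from two heterogeneous
profiles: a registry-like law (median ≈ 65, IQR 38–126) and a trial-like
law (median ≈ 25, IQR 17–43). Both are lognormals truncated below at 10
(inverse-cdf resampling) and rounded, with `(meanlog, sdlog)` calibrated
numerically so the discretized, truncated law reproduces those quartiles;
the frozen constants live in `R/scenario.R`. Exact accessors
`true_density()`, `true_cdf()` and `true_variance()` (Gauss–Hermite with
node doubling to $10^{-8}$ relative; the $\chi^2_1$ law is rewritten in a
standard-normal variable so the integrand is smooth) mean no comparison
ever relies on a simulated "truth".

What the generator does *not* emulate: patient-level covariates and
case-mix differences, correlation between a provider's size and its
performance, temporal drift, and outcome misclassification. Passing the
package's tests therefore demonstrates correct recovery of a known
two-stage binomial truth, not robustness to those real-data features.

## Metrics and the study driver

`ed_cdf()` and `ed_pdf()` integrate $(\hat F - F_p)^2$ and
$(\hat f - f_p)^2$ by composite Simpson on a fixed 2001-point grid —
fixed, because the step discontinuities of EDF-type estimates defeat
adaptive quadrature; the grid-halving error is itself tested. Densities
spilling outside $[0,1]$ are integrated against $f_p = 0$ there.
`run_study()` simulates `B` cohorts (every method sees the identical
dataset — a paired design that sharpens method contrasts), derives
per-replicate seeds from a base seed by a counter scheme for bit-for-bit
reproducibility, excludes individual fit failures with a count, and marks
a method invalid above 10% failures.

The package's own test matrix uses `B = 200` replicates with
`N = 300` providers, a deliberate desk-scale choice balancing Monte Carlo
error (tolerances are stated as three MC standard errors) against runtime;
the study driver accepts any `B`.

## Known limitations

- The normal approximation behind the MAI error model weakens for very
  small $n_i$; the small-site filter (`filter_small_sites()`, default
  minimum 10 with a median-size warning threshold) is the guard, and the
  naive convention of excluding $n_i < 25$ remains available.
- SBR and DP density estimates can show spurious modes on smooth truths;
  the variance estimates are far less affected. Inspect the SBR trajectory
  and the DP cluster-count posterior before trusting density shapes.
- No confidence intervals accompany the variance estimates, and no
  case-mix adjustment or joint modeling with provider volume is attempted.
- Finite-population summaries (the variance of the *observed* providers
  rather than the population law) are limited to what
  `population_variance()` of any estimate's support points provides.
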