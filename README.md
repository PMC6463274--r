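# providervar

Estimators of between-provider variation in binomial outcomes.

## The problem

Quality-improvement studies ask how widely a dichotomous treatment or
outcome varies across providers (hospitals, clinics, physicians). The data
are hierarchical — provider *i* contributes *y<sub>i</sub>* events among
*n<sub>i</sub>* patients:

    Y_i | p_i ~ Binomial(n_i, p_i),     p_i ~ F_p

The estimand is the distribution *F<sub>p</sub>* of the latent provider
probabilities: its variance σ<sub>p</sub>² and its density
*f<sub>p</sub>*, which is what gets plotted. The histogram of raw
proportions p̂<sub>i</sub> = y<sub>i</sub>/n<sub>i</sub> overstates the
variation (each p̂<sub>i</sub> carries binomial noise of variance about
p(1−p)/n), while the spread of empirical-Bayes shrinkage predictions
understates it. `providervar` implements both naive references and four
adjustment estimators behind one fitting front end:

| method tag | estimator |
|---|---|
| `raw` | sample proportions, 1/N-divisor variance, EDF, kernel density |
| `ghm` | Gaussian hierarchical (random-intercept logistic) model; closed-form logit-normal density, adaptive Gauss–Hermite marginal likelihood |
| `ghm_eb` | empirical-Bayes posterior-mean predictions from the GHM (the over-shrunk comparator) |
| `mai` | moment-adjusted imputation: minimally displaced values whose first *M* sample moments unbiasedly estimate the moments of *p* (default *M* = 4), via a Lagrange-constrained least-displacement problem solved by Newton–Raphson |
| `sbr` | smoothing by roughening: EM from a discrete uniform prior toward the nonparametric MLE, stopped at ν<sub>N</sub> iterations (default 50), all iterates retained |
| `dp` | Dirichlet-process beta-binomial mixture, collapsed (Polya-urn) Gibbs sampling, Gamma hyper-prior or fixed concentration, Rao-Blackwellized posterior density |

A simulation engine (`scenario_spec()`, `simulate_cohort()`) generates
cohorts from normal, standardized chi-square(1) or bimodal logit-scale
effect laws with exact density/CDF/variance accessors, and
`run_study()` compares methods over Monte Carlo replicates by bias, MSE
and integrated squared CDF/density distances.

## Worked example

```r
library(providervar)

spec <- scenario_spec("normal", sigma_b2 = 0.05, N = 300,
                      size_profile = "fixed30", seed = 1)
spec
#> scenario: normal logit effects, sigma_b2 0.05, beta0 -1.0986, N 300, sizes fixed30, seed 1
#>   true provider variance 0.001757

pc <- simulate_cohort(spec)
pc
#> provider_counts: 300 providers, 9000 patients
#>   site size: median 30 (IQR 30-30)
#>   raw proportion: mean 0.2506, range 0.0333-0.5333

fit_pdist(pc, method = "raw")
#> pdist [raw]: mean 0.2506, variance 0.007722 (sd 0.0879)
fit_pdist(pc, method = "mai")
#> pdist [mai]: mean 0.2506, variance 0.001720 (sd 0.0415)
fit_pdist(pc, method = "ghm")
#> pdist [ghm]: mean 0.2506, variance 0.001512 (sd 0.0389)
```

The true variance of the provider probabilities in this scenario is
0.001757. The raw proportions report 0.0077 — over four times too large,
because each site's estimate carries binomial noise of variance about
0.1875/30 ≈ 0.0063. Moment-adjusted imputation removes that noise by
construction and lands at 0.00172; the hierarchical model's logit-normal
variance is similarly close. `summary()`, `coef()`, `predict()`, `plot()`
and `simulate()` work on every fitted estimate:

```r
summary(fit_pdist(pc, method = "mai"))
#> Estimated provider-probability distribution (method: mai)
#>   mean 0.2506  variance 0.001720  sd 0.0415
#>   quantiles:
#>   2.5%    25%    50%    75%  97.5%
#> 0.1795 0.2110 0.2424 0.2739 0.3368
```

Before fitting the Dirichlet-process model, check what a hyper-prior
implies about the number of provider clusters:

```r
prior_cluster_distribution(100, dp_config(preset = "dp2"),
                           n_draws = 20000, seed = 1)
#> Prior clusters for N=100 (20000 draws): median 69, 95th pctile 80, central 95% [52, 82]
```

A thin command-line wrapper over the same functions lives at
`inst/cli/providervar.R` (subcommands `estimate`, `simulate`, `study`,
`dp-prior-clusters`).

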