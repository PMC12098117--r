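# floodlag

Two-stage distributed lag non-linear models (DLNM) for estimating delayed
health effects of flood exposure from multi-community daily hospitalization
time series.

Floods raise hospitalization risks for months after the water recedes —
through contaminated water, displacement, interrupted care and psychological
stress. `floodlag` implements the standard two-stage design used to quantify
such delayed risks:

1. **Stage 1, per community**: a quasi-Poisson regression of daily counts on
   a flood *cross-basis* — the tensor product of a strata exposure basis
   (not exposed vs exposed, optionally split by flood severity) and a
   natural cubic spline lag basis (df 4, with intercept, log-spaced knots)
   over lags 0–210 days — adjusted for temperature and precipitation
   cross-bases (lags 0–21 and 0–14 days), a cubic B-spline trend (df 3), a
   cyclic cubic B-spline seasonal term (3 equally spaced knots) and
   day-of-week indicators. For day *t*:

   `log E[Y_t] = α + Σ_l f(x_{t−l}, l) + confounders(t)`, `Var[Y_t] = φ E[Y_t]`

2. **Stage 2**: the community-specific flood coefficient vectors `η_i` and
   covariances `S_i` are pooled by multivariate random-effects
   meta-analysis, `η_i ~ N(β, S_i + Ψ)`, with Ψ estimated by restricted
   maximum likelihood (log-Cholesky parametrization, multi-start BFGS).
   Heterogeneity is summarized by Cochran's Q and I²; effect modification is
   tested by meta-regression on the cumulative log relative risk.

From the pooled fit the package derives lag-specific relative-risk curves
`RR(l) = exp(w(l)ᵀβ)`, the cumulative relative risk over the lag window
`cumRR = exp(Σ_l w(l)ᵀβ)` (the product of per-lag RRs), and
backward-perspective attributable fractions
`AF = 100 · Σ_t n_t (1 − exp(−Σ_l w(l)ᵀβ x_{t−l})) / Σ_t n_t`
with Monte-Carlo empirical confidence intervals from multivariate-normal
coefficient draws.

Because community-level hospitalization records are confidential almost
everywhere, the package ships a first-class synthetic-data generator
(`generate_panel()`) that emulates multi-year daily panels — seasonality,
day-of-week structure, trend, weather confounding, negative-binomial
overdispersion, flood episodes, between-community heterogeneity — with a
*planted* lag-response curve, plus analytic truth oracles
(`analytic_truth()`) and calibration (`calibrate_to_target()`) so the whole
pipeline is validated by parameter recovery.

## Worked example

Simulate ten communities over three years with a planted 210-day cumulative
relative risk of 1.26, run the full two-stage pipeline, and read off the
pooled results:

```r
library(floodlag)

cfg <- sim_config(n_communities = 10, years_per_community = 3, seed = 1) |>
  calibrate_to_target(target_cum_rr = 1.26)
sim <- generate_panel(cfg)

res <- run_flood_pipeline(sim$panel, covariates = sim$covariates,
                          af_draws = 500, af_seed = 7)

res$cum_rr
#> # A tibble: 1 × 5
#>   cause level   estimate ci_low ci_high
#>   <chr> <chr>      <dbl>  <dbl>   <dbl>
#> 1 all   exposed     1.31  0.812    2.11

res$heterogeneity
#> # A tibble: 1 × 7
#>   cause     Q  df_Q    I2 p_value     k     d
#>   <chr> <dbl> <int> <dbl>   <dbl> <int> <int>
#> 1 all    36.0    32  11.0   0.288     9     4

res$af
#> # A tibble: 1 × 6
#>   cause level      af eci_low eci_high attributable_number
#>   <chr> <chr>   <dbl>   <dbl>    <dbl>               <dbl>
#> 1 all   exposed 0.337  -0.268    0.992                399.
```

The pooled 210-day cumulative relative risk is 1.31 (95% CI 0.81–2.11),
straddling the planted truth of 1.26 — ten communities is deliberately
small, so the interval is wide. One of the ten communities drew no flood
episodes and was excluded (`k = 9`). Between-community inconsistency is
mild (I² = 11%). An estimated 0.34% of hospitalizations (95% empirical CI
−0.27 to 0.99) are attributable to floods, against a planted analytic truth
of 0.28%; about 399 admissions per year across the panel.

`autoplot(res$lag_curves)` draws the lag–response curve with its CI ribbon;
`plot_cum_rr()` and `plot_af()` give forest-style summaries. `tidy()` and
`glance()` methods expose stage-1 and pooled fits as tibbles.

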