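---
title: "Two-stage distributed-lag models for flood-related hospitalization risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage distributed-lag models for flood-related hospitalization risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floodlag)
library(dplyr)
```

## The problem

Floods affect health well beyond the days a community is under water:
contaminated water supplies, displacement, interrupted care for chronic
conditions and psychological stress raise hospitalization risks for weeks to
months after the water recedes. Quantifying that delayed risk from routine
data takes three ingredients:

1. a **daily exposure series** per community — a day is a *flooded day* when
   it falls between a flood event's official start and end dates (inclusive);
   when events of different severity overlap, the higher severity wins;
2. a **community-level time-series regression** that spreads the effect of a
   flooded day over a long lag window while controlling for seasonality,
   long-term trends, day of week and weather;
3. a **meta-analytic second stage** that pools the community-specific
   coefficient vectors into an overall lag–response association, with
   heterogeneity statistics and effect-modification contrasts.

`floodlag` implements this two-stage design together with the downstream
impact measures (lag-specific relative risks, cumulative relative risks,
attributable fractions) and a synthetic-data generator that plants known
truths so every stage can be validated by parameter recovery. Communities
that never flood carry no information about the flood coefficients and are
excluded before stage 1 (`exclude_unflooded()` reports them).

## Stage 1: quasi-Poisson regression with a flood cross-basis

For one community, daily counts $Y_t$ are modelled as overdispersed Poisson,
$\operatorname{E}[Y_t] = \mu_t$, $\operatorname{Var}[Y_t] = \phi\,\mu_t$, with

$$
\log \mu_t = \alpha
 + \sum_{l=0}^{L} f(x_{t-l}, l)
 + \text{cb}_{\text{temp}}(t) + \text{cb}_{\text{precip}}(t)
 + s_{\text{trend}}(t) + s_{\text{season}}(\text{doy}_t)
 + \gamma_{\text{dow}(t)} .
$$

The flood term $f$ is a **cross-basis**: the tensor product of an exposure
basis and a lag basis. Its coefficients encode the full exposure–lag–response
surface.

* **Exposure dimension** — a strata (indicator) basis: not exposed is the
  reference, so the basis carries no intercept. The main analysis uses two
  strata (not exposed / exposed); a three-strata variant separates lower- and
  higher-severity flooded days.
* **Lag dimension** — a natural cubic spline over lags $0..L$ with $L = 210$
  days and dimension 4, *including* an intercept column. Interior knots sit
  at equally spaced values of $\log(\text{lag})$ between $\log 1$ and
  $\log L$, the established convention for long lag windows: it concentrates
  flexibility at short lags, where risk changes fastest, while keeping the
  210-day tail smooth. Both the intercept and the knot rule are config
  switches (`crossbasis_spec()`) because reasonable analyses differ here;
  sensitivity runs can flip them.

Confounder control follows standard practice for daily hospitalization
series: a cubic B-spline with 3 df over each community's own study span for
long-term trend; a cyclic cubic B-spline with three equally spaced knots for
day of year (the cyclic basis is a partition of unity, so one column is
dropped in the design to avoid collinearity with the intercept — the spanned
space is unchanged); six day-of-week indicators with Monday as the fixed
reference; and two further cross-bases for daily mean temperature (lags
0–21 days) and precipitation (lags 0–14 days). The weather cross-bases use
natural cubic splines with 3 df in both dimensions by default — only the
maximum lags are canonical; the dfs are configurable. Because precipitation
is zero-inflated, quantile-placed spline knots can collapse onto the
boundary; `ns_basis()` then falls back to equally spaced interior knots.

Days whose 210-day lag history reaches before the series start have no
complete exposure history. By default those rows are dropped from the
likelihood (a config option keeps them with truncated lag sums); the
synthetic generator prepends a flagged burn-in of $L$ days so that the
nominal study span is fully usable.

Fitting uses iteratively reweighted least squares (`stats::glm.fit`,
relative deviance tolerance $10^{-9}$, at most 100 iterations). Point
estimates are identical to Poisson maximum likelihood; the dispersion
$\hat\phi$ is the Pearson statistic over residual degrees of freedom and
inflates the coefficient covariance, $\widehat{\operatorname{Var}}(\hat\eta)
= \hat\phi (X^\top W X)^{-1}$. Zero-count days are ordinary observations (the
model is for counts, not rates; no offset). A fit is excluded from pooling,
with a logged reason, when IRLS does not converge, the design is rank
deficient, or the flood-block covariance is numerically singular (condition
number above $10^{10}$) — standard hygiene in two-stage designs.

## Stage 2: multivariate random-effects meta-analysis

Each community contributes its flood-block coefficient vector
$\hat\eta_i \in \mathbb{R}^d$ (here $d = 4$) and covariance $S_i$. The
pooling model is $\hat\eta_i \sim N(\beta,\; S_i + \Psi)$ with
between-community covariance $\Psi$, estimated by restricted maximum
likelihood. Numerical choices:

* $\Psi$ is parametrized by its Cholesky factor with log-transformed
  diagonal, so every candidate is positive semi-definite by construction;
* the restricted log-likelihood is maximized by BFGS from five deterministic
  starting points (the empirical between-community spread scaled by 1, 0.1,
  10, 0.01 and 3), taking the best optimum — restarts guard against flat
  or multimodal surfaces without touching the RNG, so results are
  bit-reproducible and invariant to community order (inputs are sorted
  canonically before pooling);
* with $k \le d$ communities $\Psi$ is not identifiable and the model falls
  back to a proportional (scalar × identity) form with a warning; a single
  community passes through degenerately ($\beta = \hat\eta_1$, $\Psi = 0$).

Heterogeneity is quantified by Cochran's $Q$ evaluated at the fixed-effect
(inverse-variance) solution, with $df = d(k-1)$, and
$I^2 = \max(0, (Q - df)/Q) \times 100$ — the standard multivariate
generalization, truncated at zero. An $I^2 \ge 40\%$ is conventionally read
as moderate-or-strong inconsistency.

**Effect modification.** `meta_regression()` pools the fits per level of a
community-level modifier and tests each level against the reference on the
derived *cumulative log relative risk* — a scalar Wald contrast rather than
the full $d$-vector, matching how per-stratum results are usually reported
and keeping power interpretable. Modifiers observed on different populations
(climate, density, socioeconomic halves) use a random-effects pool per
level; flood-severity strata are estimated on the same populations, so a
fixed-effect ($\Psi = 0$) pool is used there. No small-sample (Knapp–Hartung
type) correction is applied by default; meta-regressions are not adjusted
for country. Numeric covariates are grouped by `cut_groups()`: tertiles for
population density, a median split for socioeconomic measures.

## Impact measures

With pooled coefficients $\beta$ and lag-basis row $w(l)$:

* **lag-specific RR**: $\log \text{RR}(l) = w(l)^\top \beta$, with
  delta-method CIs $\exp(w^\top\beta \pm 1.96\sqrt{w^\top V w})$;
* **cumulative RR** over the window: the *product* of per-lag RRs, i.e.
  $\log \text{cumRR} = (\sum_l w(l))^\top \beta$. Cumulating on the log
  scale is the only definition consistent with multiplicative risks — a
  naive sum of 211 per-lag RRs near 1 would approach 211, not a risk ratio;
* **attributable fraction** (backward perspective): each day's exposure
  history contributes
  $AN_t = n_t\,(1 - \exp(-\sum_l w(l)^\top\beta\, x_{t-l}))$ and
  $\text{AF} = 100 \sum_t AN_t / \sum_t n_t$, with $n_t$ the observed
  counts. The backward (exposure-history) perspective is the natural one for
  a daily exposure series. The 95% *empirical* CI takes the 2.5/97.5
  percentiles of the AF recomputed under coefficient draws
  $\beta^{(b)} \sim N(\beta, V)$ — 1000 draws by default, a fixed seed
  giving identical bounds; only pooled-coefficient uncertainty is resampled,
  not stage-1 sampling variation. In multi-country analyses the AF is meant
  to be computed per country from that country's pooled coefficients
  (`pool_by_grouping()`) applied to its own communities' exposure and
  counts, then aggregated.

Internal consistency identities (`cum_rr` equals the product of `lag_rr`
values; zero coefficients give cumRR $= 1$ and AF $= 0$ exactly) are
asserted in the test suite.

## The synthetic-data generator

Real hospitalization records at community level are confidential almost
everywhere, so the package treats simulation as a first-class citizen:
`generate_panel()` emulates the *structure* of a multi-country daily panel
and plants a known lag-response so the full pipeline can be checked by
recovery.

Per community it draws: flood episodes (Poisson number per community-year,
uniform placement, geometric durations, Bernoulli severity mix); seasonal
AR(1) temperature and zero-inflated right-skewed precipitation; and counts
that are negative binomial with variance $\phi\mu$ — the same first two
moments stage 1 assumes ($\phi = 1$ collapses to Poisson). The planted
lag-response enters the log rate as the convolution of the exposure
indicator with a per-lag log-RR curve, scaled per community by a log-normal
multiplier with mean-zero log (SD `heterogeneity_sd`), which is exactly the
between-community variation $\Psi$ pools in stage 2. All structural
randomness (events, weather, multipliers, covariates) is drawn before any
counts, so the realized exposure pattern depends only on the seed — the
calibration machinery relies on this.

Default conditions (40 communities × 6 years, baseline 30 admissions/day,
overdispersion 1.5, heterogeneity SD 0.1, episodes 0.6/community-year
lasting ~5 days, 20% higher-severity) describe a mid-sized national
hospital panel; community-level count magnitudes are a package choice since
published studies report only aggregates. What the generator does *not*
emulate: spatial flood footprints, weather reanalysis realism, holidays,
reporting artefacts, or correlated exposure between neighbouring
communities. Recovery results therefore demonstrate correctness of the
estimator under its own assumptions — not robustness to the
misspecifications real data bring.

**Oracles and calibration.** `analytic_truth()` computes the planted
cumulative RR in closed form and the planted AF by brute-force day-by-day
summation over the realized exposure. `calibrate_to_target()` scales the
planted curve so the truth hits a requested value: cumulative-RR targets
have a closed form (scale $= \log(\text{target}) / \sum_l g(l)$);
AF targets are solved by `uniroot` on the curve scale against the realized
exposure pattern, exact to $10^{-6}$ percentage points. The curve scale —
not the episode rate — is the root-search variable for AF because the
realized AF is continuous and strictly monotone in the scale, whereas it
moves in discrete jumps with the episode rate (episodes are whole events);
the episode rate stays an explicit design input.

## Recovery studies (what `scripts/acceptance.R` runs)

The script re-runs the full pipeline on calibrated panels at the default
scale, 5 panel seeds per target, and reports the mean recovered estimate:

* cumulative RR targets 1.26 and 1.61 with an exponential-decay planted
  curve (rate 1/60 per day), and 1.11 with a Gaussian-bump curve centred at
  lag 60 (SD 40 days) — the delayed-onset shape;
* AF targets 0.27% (episode rate 1/community-year) and 1.93% (rate
  3/community-year; the larger rate keeps the calibrated curve in a
  realistic range for a large attributable burden), with 1000 coefficient
  draws for the empirical CI.

Each run is 40 communities × 6 years of daily data (438,000 community-days
per target across the 5 seeds) — large enough that the Monte-Carlo SE of
the 5-seed mean is a few percent, small enough for a desk-scale run. The
same protocol, at the same scale, backs the acceptance test suite, together
with oracle-equivalence checks (cross-basis vs direct convolution, splines
vs truncated-power/de Boor constructions, REML vs a univariate profile
search and `metafor`), exact closed forms, and calibration checks (mean
$Q \approx df$ under homogeneity, uniform null difference p-values,
empirical-CI coverage between 90% and 99% over 200 small-panel
replicates — those replicates plant a curve inside the lag-spline span so
coverage is not confounded by projection error).

## Known limitations

* The lag spline ($df = 4$ over 211 lags) can only recover curves up to its
  span; sharp or oscillatory planted shapes incur projection bias. The
  recovery tests quantify this for smooth shapes (a few percent at most).
* The empirical AF interval propagates pooled-coefficient uncertainty only.
* `meta_regression()` treats modifier levels as independent pools; shared
  communities between levels (as with severity strata) are handled via the
  fixed-effect mode but overlapping populations are not otherwise modelled.
* Between-community covariance estimation at $k$ close to $d$ is fragile;
  the proportional fallback trades realism for identifiability.
* Calendar handling assumes contiguous daily series; gaps must be handled
  upstream (validation rejects them).

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_communities = 10, years_per_community = 3, seed = 1) |>
  calibrate_to_target(target_cum_rr = 1.26)
sim <- generate_panel(cfg)

res <- run_flood_pipeline(sim$panel, covariates = sim$covariates,
                          af_draws = 500, af_seed = 7)
res$cum_rr        # pooled 210-day cumulative RR with CI
res$heterogeneity # Cochran's Q, I^2
res$af            # attributable fraction with empirical CI
autoplot(res$lag_curves)
```
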