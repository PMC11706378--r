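---
title: "Methods: doubly-robust DiD for composite health-security scores and immunization coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: doubly-robust DiD for composite health-security scores and immunization coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the model behind the estimator, the assumptions it leans on, the tunable
parameters and why their defaults are what they are, what the synthetic
generator does and does not emulate, and the numerical and design choices
made where more than one reasonable convention exists.

## The design

The data are a long panel of childhood immunization coverage
`Coverage_it` (percent of the target cohort, 0–100) for country–vaccine
series `i` over years `t` = 2015–2022.  The motivating outcome model is a
two-way fixed-effects specification

```
Coverage_it = alpha + gamma_t + delta_i + theta * Treated_i x Post_t + X_i' beta + eps_it
```

with common year effects `gamma_t`, unit effects `delta_i`, covariates
`X` (World Bank income group, WHO region), and treatment defined by a
composite health-security score at or above a cutoff; `Post` is
2020–2022.  Estimation, however, does not run this regression.  Each
post-year effect is estimated as a separate 2×2 comparison using the
doubly-robust ATT estimator: for base year `b` (the last pre-pandemic
year) and target year `t`,

```
ATT(b, t) = sum_i (w1_i - w0_i) * (dY_i - mu_hat(X_i)),   dY_i = Y_it - Y_ib
```

* `w1_i = D_i / sum(D)` weights treated units equally;
* `w0_i` is proportional to the propensity odds `p_hat(X_i) / (1 - p_hat(X_i))`
  over control units, normalized to sum to one, so the reweighted controls
  match the covariate distribution of the treated;
* `mu_hat(X)` is the least-squares fit of `dY` on the dummy-encoded
  covariates among controls.

Differencing removes `delta_i` and any time-invariant `X beta`;
the weighting/adjustment removes covariate-linked differences in
*trends*.  The estimate is consistent if either the propensity model or
the outcome model is correctly specified (double robustness), which is
the property the package's misspecification tests exercise directly.

Identification rests on parallel trends conditional on covariates.  The
design tests it: placebo ATTs are computed for every adjacent pre-year
pair (2015→2016, …, 2018→2019) and combined in a joint Wald statistic
`W = theta' V^-1 theta`, with `V` estimated from the stacked influence
functions clustered by country.

## Inference, and one deliberate calibration choice

Per-estimate standard errors come from the estimator's influence
function, aggregated to country clusters (countries, not country–vaccine
series, are the independent units; all twelve series of a country share
its treatment status).  95% intervals are `estimate ± 1.96 se`.  A
country-cluster bootstrap (`cluster_bootstrap_se()`) is provided as a
cross-check; analytic inference is the default, and on synthetic panels
the two agree within a few percent.

The joint pre-trend statistic is a different matter.  Referring `W` to a
chi-square with one degree of freedom per placebo assumes `V` is known.
In this design, the covariance is effectively estimated from *few*
clusters: with a high cutoff only ~20–30 treated countries exist, and the
odds-reweighting concentrates the control-side information on a similar
number of high-propensity countries.  Measured over 400 simulated panels
at study scale, the chi-square reference rejected true parallel trends
about 11% of the time at the nominal 5% level — a Hotelling-T² situation,
not a miscalculation (with the true covariance the same statistics reject
5.7%).  The package therefore defaults to the Hotelling-style
small-sample reference: `W (G - K) / (K (G - 1)) ~ F(K, G - K)`, where
`G` is the *effective* number of clusters — the participation ratio
`(sum_c g_c)^2 / sum_c g_c^2` of each country's total design weight
`g_c = sum_{i in c} (w1_i + w0_i)` — about 67 on study-scale panels,
together with the Wishart-style `G/(G-1)` covariance factor.  Measured
size: 6.5%.  `pretrend_test(..., reference = "chisq")` gives the
uncorrected version for comparison.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| year window | 2015–2022 | years | 5 pre-pandemic years for the placebo test, 3 post years |
| post period | 2020–2022 | years | pandemic onset defines pre/post |
| base year (post effects) | 2019 | year | last pre-pandemic year, the standard group-time convention |
| base year (placebos) | rolling `t-1` | year | adjacent-pair placebos localize violations in time |
| covariates | income group, WHO region | categorical | the study design's confounders; dummy-encoded, reference = alphabetically first level |
| propensity clip | [0.001, 0.999] | probability | covariate cells with no treated countries (e.g. low-income cells at high cutoffs) get near-zero weight instead of failing |
| cutoff grid | 0–100 step 1 (scores); −2.5–2.5 step 0.1 (governance) | score units | full scale at the reporting resolution of each scale |
| `min_group` gate | 5 treated and 5 control countries | countries | below this, 2×2 fits are dominated by single clusters |
| `pretrend_alpha` | 0.05 | level | pass requires `p >= 0.05`; a model at exactly 0.05 passes |
| significance rule | average-effect 95% CI above 0 | — | pooled effect is the headline estimand; `any_year` available |

Ties at the cutoff are treated (`score >= cutoff`).  Cutoff percentiles
are reported as the fraction of countries *strictly below* the cutoff,
rounded to two decimals; this convention reproduces published-style
percentile labels to within one unit in the second decimal (conventions
differ in the last rounding digit and no single one is canonical).

The averaged 2020–2022 effect is the exact unweighted mean of the three
yearly ATTs — so a printed average can always be audited against its
printed yearly effects — with its variance taken from the averaged
influence functions (which respects the strong correlation induced by
the shared 2019 base year).

The analysis unit is the country–vaccine series (12 per country) with
country-level clustering; a per-country mean-coverage unit is available
(`unit = "country_mean"`).  The series-level unit keeps vaccines with
different baseline levels from averaging away heterogeneous declines,
and clustering absorbs the dependence.

## The synthetic generator

`synthetic_truth()` + `generate_panel()` emulate the statistical
structure the estimator assumes, at the study's scale (191 countries ×
12 vaccines × 8 years = 18,336 cells):

* hierarchical scores: 96 Beta-distributed sub-indicators on [0, 100]
  around a country mean combining a latent ability (sd 10) with an
  income-group shift of ±`confounding` points (default 12), aggregated
  by equal-weight means — giving an overall-score distribution with mean
  ≈ 41 and sd ≈ 13.5 and a treated share at the default threshold 57 of
  ~12%, matching the shape of the real index;
* coverage: intercept 82, gentle common pre-trend, pandemic-year dips
  (−2.3, −3.6, −2.8), country effects (sd 1.5), vaccine effects (sd 1.5),
  observation noise sd 3;
* confounding that matters: income shifts both the score *and* the
  post-period drop (`beta_post`: high-income 0 to low-income −3), so the
  naive unadjusted difference-in-means DiD is biased while the
  covariate-adjusted doubly-robust estimate is not — the package's tests
  demonstrate exactly this;
* planted per-year effects `tau = (0.74, 1.23, 0.76)` for countries at or
  above the threshold, on the scale of published estimates;
* optional differential pre-2020 slopes (`pretrend_slope`) to give the
  pre-trend test something to detect, and sparse missingness injection
  (e.g. the 12-country BCG-2022 reporting gap, 0.07% of cells).

Coverage is clipped to [0, 100]; defaults keep clipping below 0.1%, a 1%
rate warns, and 10% errors.  All randomness flows from the single seed in
`synthetic_truth()`.

What the generator does **not** emulate — and what passing tests
therefore cannot certify about real data: the strong right-skew and
15-point spread of real coverage distributions (synthetic levels are
tighter and lower; level constants cancel in every difference-based
quantity, but descriptive group means sit below the published ones);
serially correlated country-year shocks; reporting artifacts such as
coverage heaping at 99; and any real mechanism linking health-security
capacity to immunization outcomes.  The generator validates the
*machinery*, not the substantive conclusion.

Test and acceptance problem sizes are the package's own choices: 500
replicates for effect-recovery calibration (per-year bias ≈ 0.02,
interval coverage 0.94–0.96), 1,000 for pre-trend size, 200 for
misspecification bias at n = 5,000 units, 20 seeds for
threshold-recovery sweeps, 199 draws for the bootstrap cross-check.

## Known limitations

* **The qualifying rule does not localize a planted threshold.**  For an
  effect planted at score `s*`, every cutoff `c < s*` still nets all
  truly affected countries into the treated group, so the estimand at `c`
  is the diluted ATT `tau * P(score >= s* | score >= c) > 0`; at study
  scale its z-statistic exceeds 2 far below `s*`, and the minimum
  *significant* cutoff lands tens of points below the planted threshold.
  No smooth score distribution avoids this: a significance crossing that
  sits *at* the threshold requires the z-curve to cross 2 there, and a
  curve that crosses gently is moved by tens of points from seed to seed.
  The threshold is instead visible as the plateau/kink of the
  effect-vs-cutoff curve.  The minimum qualifying cutoff should be read
  as "the least demanding cutoff at which a protective effect is
  detectable", not as an estimate of where the effect begins.
* Sweeps over many cutoffs and many score variables perform no
  multiplicity correction (matching reporting practice for this design);
  per-cutoff intervals are pointwise, not uniform bands.
* The pre-trend gate is a test of *detectable* violations; passing it at
  ~25 treated countries leaves power for only moderately large
  violations (a 0.5-point/year differential slope is detected ≥ 80% of
  the time at study scale; smaller ones often pass).
* Missing cells are dropped pairwise per 2×2 fit (with tallies), not
  imputed; a vaccine series missing its base year drops out of every
  post-year contrast.
* The local-polynomial trend curves (`loess_trend`, tricube weights,
  span 0.75, degree 2 — the caption-style smoother) describe the sweep
  output; their pointwise standard errors ignore the correlation between
  estimates at neighbouring cutoffs, which share almost all their data.
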