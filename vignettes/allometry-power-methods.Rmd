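---
title: "Methods: subsampling power analysis of ontogenetic allometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subsampling power analysis of ontogenetic allometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Cross-sectional ontogenetic allometry is usually inferred by regressing the
logarithm of a trait against the logarithm of a reference size variable
across individuals at different growth stages. For linear measurements of
equal dimension, a slope of 1 is isometry (geometric similarity) and is
conventionally the null hypothesis; slopes credibly above or below 1 are
positive or negative allometry. Fossil and rare-taxon samples are small, and
because isometry is the null, low power converts real allometry into
spurious "isometry" — a Type II-like failure this package calls *false
isometry*. `allopower` quantifies that failure by Monte-Carlo subsampling of
a well-sampled ontogenetic series: how small can a sample get before the
full-sample scaling category stops being recovered?

## Line fitting and classification

Both ordinary least squares (OLS) and standardized major axis (SMA) fits are
provided, computed from the closed-form sums on pairwise complete log-log
pairs. For OLS, the slope CI and the two-sided test of slope = 1 use the
usual t machinery on `n - 2` degrees of freedom. For SMA the slope is
`sign(r) * sd(v)/sd(u)`, the 95% CI is `slope * (sqrt(B + 1) -/+ sqrt(B))`
with `B = F(0.95; 1, n - 2) (1 - r^2)/(n - 2)`, and the slope-vs-1 test is
the correlation test between the residual axis `v - u` and the fitted axis
`v + u`. These are the standardized (Warton-style) formulas; interval and
test are dual on the positive-slope branch, which is the allometric regime
(near-perfectly correlated positive log-log relations). For negative fitted
slopes the magnitude-based test and the signed interval can disagree; such
fits are outside the method's intended domain and are surfaced unchanged.

Classification is interval-based and inclusive: positive allometry iff the
whole 95% CI lies above 1, negative iff below, isometric otherwise (a CI
endpoint exactly at 1 is isometric). Isometric results are subdivided:
*soft isometry* when the slope-vs-1 p-value is below 0.15 (the
non-rejection plausibly reflects low power and may flip with more data) and
*hard isometry* otherwise. The 0.15 boundary is a configurable convention:
any threshold between roughly 0.12 and 0.22 reproduces the printed
subtype labels of the published alligator table, and 0.15 sits centrally in
that interval. Significance stars follow the conventional four-level scheme
(`*` < 0.05 through `****` < 0.0001).

## Subsampling schemes and the replicate engine

Four without-replacement schemes emulate different sampling regimes over
the reference-size axis:

* **random** — uniform over specimens; the baseline.
* **even_length** — the size range is cut into `n` equal-width bins
  (half-open except the last) and one specimen is drawn per bin; the
  best-case design, errors when a bin is empty.
* **even_occupancy** — specimens sorted by size (stable in input order for
  ties) are cut into `n` equal-occupancy bins with boundaries at
  `round(i N / n)` (round-half-to-even, R's native rounding); one draw per
  bin.
* **adult_biased** — `n - 1` draws from the "adult" class (size at or above
  half the maximum — the boundary itself counts as adult, since the small
  class is defined by *less than* half) and exactly one from the juvenile
  class; emulates taphonomic loss of juveniles.

Default sweep ranges are random 3–100, even-occupancy and adult-biased
3–20, even-length 3–10, at 1,000 replicates per size (configurable; the
bundled analyses and tests use 200–300 replicates, which sets the
resolution of a proportion at 0.5 percentage points and keeps the full
pipeline inside a couple of minutes). Every replicate draws its own RNG
substream derived by hashing `(master seed, scheme, variable, n)` plus an
affine per-replicate step, so any single replicate can be reproduced in
isolation; a naive reference loop over the same substreams reproduces the
engine's tallies exactly (this is a test). Replicates whose subsample is
degenerate (e.g. zero variance after rounding) are counted as failed and
excluded from the category denominator; subsample sizes infeasible for a
binned scheme are recorded as skipped rather than aborting the sweep.

## Minimum sample size and error rates

Per variable and scheme, the proportion of replicates in each category
traces an *allometric power plot* against subsample size. The
minimum-sample-size statistic is the **first** sweep size at which the
proportion agreeing with the full-sample ("true") category reaches 0.95 —
first crossing, no persistence requirement (a persistent variant exists
behind a flag for sensitivity analysis). It is reported censored
(`"> nmax"`) when never reached and is undefined for isometric truths,
isometry being the null. The error taxonomy is definitional: for allometric
truths, *false isometry* (the Type II analogue) and *sign error*; for
isometric truths, *false allometry* (the Type I analogue). Aggregation
across variables is the unweighted mean and sample SD per sweep size.

The truth is always the full-sample classification, not the generating
parameter: the approach treats the complete series as the best available
estimate, and subsample deviations from it as small-sample error. Synthetic
validation tests additionally compare against the generating slope, where
the two notions coincide by construction.

## The minimum-n-versus-slope law

Across variables, minimum sample size against fitted slope follows an
inverse-hyperbolic law, `y = m/|x - b|` (eq1) or `y = m/|x - b| + c` (eq2),
with the vertical asymptote `b` expected just below 1: near-isometric
slopes need arbitrarily many specimens. The objective is non-smooth at the
data abscissae, so the fit profiles `b` over a 201-point grid spanning the
abscissa range (poles excluded), solves `m` (and `c`) linearly at each grid
point, refines the best candidate by Nelder-Mead (relative tolerance
1e-12), and re-polishes the linear parameters at the refined `b`. For eq2
the eq1 optimum with `c = 0` is also tried as a start, which guarantees the
nested model never fits worse. Parameter CIs are asymptotic
(Jacobian-based covariance, t quantiles). Censored minimum-n values are
**excluded** from fitting rather than truncated to their sweep bound —
truncation would fabricate data points at the censoring limit.

Model comparison uses the Gaussian concentrated-likelihood AIC,
`n ln(rss/n) + 2k` with `k` counting curve parameters plus the residual
variance. Absolute AIC values are therefore defined only up to an additive
constant, but delta AIC and Akaike weights — the quantities interpreted —
are constant-free for models sharing a point set.

## Synthetic data: what it emulates and what it does not

The generator is exactly the analysis model: reference sizes from a chosen
distribution on 29–689 mm (log-uniform by default; optionally uniform,
adult-skewed via a Beta(alpha, 1) density on log size, or resampled from a
user-supplied empirical size vector), and each variable as
`log10 y = a + b log10 L + Normal(0, sigma)`, optionally rounded to 1 mm
(clamped at 1 mm) to emulate field precision. Matching generator and
analysis model makes parameter recovery a well-posed check: OLS slope
estimates are unbiased and their CIs attain nominal coverage of `b` (both
tested). The residual scale is parameterized through the target R-squared,
`sigma = |b| sd_u sqrt((1 - R2)/R2)`; `alligator_like_spec()` instantiates
22 variables from the published full-sample intercept/slope/R-squared table
with the default `sd_u = log10(689/29)/sqrt(12)`, the SD of the log-uniform
size distribution.

One coverage subtlety: under this generator all residual noise is vertical,
so the SMA estimand is the population SD ratio
`sqrt(b^2 sd_u^2 + sigma^2)/sd_u`, slightly above `b`. The SMA interval is
calibrated for that estimand (tested), not for `b`; at the R-squared values
typical here the difference is under 1%, but coverage tests must target the
right quantity.

What the generator does **not** emulate: covariance among variables (noise
is independent per variable, while real skull measurements co-vary),
heteroscedastic or non-normal residuals, the real series' uneven size
sampling (available via the empirical-weights option if a size vector is
supplied), and measurement error beyond symmetric 1-mm rounding. Passing
synthetic tests therefore demonstrate correctness of the machinery and
qualitative transferability, not that real data meet the model's
assumptions — the real series is in fact reported to fail normality checks.

The survey generator draws integer sample sizes as
`round(exp(Normal(mu, s)))` clamped at a per-cell minimum, with defaults
(`default_survey_spec()`) chosen by the log-normal moment identities
`mu = ln(median)`, `s = sqrt(2 ln(mean/median))` from the published
per-cell medians and means (542 samples total; minima 6/6/3/4). The
log-normal shape reproduces location and right skew but not the exact tail
weight, so the simulated share of samples at `n <= 10` deviates from the
published percentages even though medians and means match.

## Survey comparisons

Group summaries are N, min, max, mean, median and the share with
`n <= 10`. Distribution comparisons use the two-sample two-sided
Kolmogorov-Smirnov test with the asymptotic p-value (`stats::ks.test`,
`exact = FALSE`): integer sample sizes carry heavy ties, under which exact
small-sample p-values are undefined. At two samples of 100 the asymptotic
test is conservative — its exact null rejection rate at alpha = 0.05 is
3.6%, because rejection requires the discrete event D >= 0.2 — which is
why the calibration test simulates enough pairs to resolve that rate
precisely. Significance bands in reports: `***` p < 0.001, `*` p < 0.05.

## Problem sizes and numerical conventions

The bundled analyses and acceptance checks run at: 108 specimens, 22
variables; 200 sweep replicates (300 for the ten-slope asymptote-recovery
study, 1,000 per repetition in the false-isometry monotonicity study);
sweeps of 3–100 (random; 3–60 where the minimum n is known to lie well
below 60) and the scheme-specific defaults otherwise; 2,000 datasets for CI
coverage; 40,000 pairs for KS calibration. Logarithms are base 10
throughout (slopes are base-invariant; intercepts are reported base-10).
Rounding of occupancy boundaries is round-half-to-even. Ties in size
sorting break by input order. All randomness flows from one master seed
through named substreams, so every table, sweep and replicate is exactly
reproducible.

## Known limitations

* SMA p-values address the slope magnitude branch; datasets with negative
  fitted slopes (absent in practice for growth data) are not handled
  specially.
* The minimum-n statistic inherits Monte-Carlo noise of order
  `sqrt(0.05 * 0.95 / reps)` around the 95% crossing; at 200 replicates a
  crossing within about 1.5 percentage points of the level can shift the
  reported minimum by a few specimens between seeds.
* Censored minimum-n values carry no partial information into the
  hyperbolic fit (they are dropped, not modeled); a survival-style
  treatment is out of scope.
* The asymptotic KS p-value is conservative at moderate sample sizes, as
  quantified above.
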