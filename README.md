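# allopower

How many specimens does it take to detect ontogenetic allometry? `allopower`
answers that question by Monte-Carlo subsampling: it fits bivariate log-log
allometries (OLS and standardized major axis), classifies each trait as
positively allometric, negatively allometric, or isometric from the 95%
confidence interval of the slope, and then measures how reliably ever-smaller
subsamples of a well-sampled ontogenetic series recover the full-sample
category. The motivating problem is palaeobiological: fossil samples are
systematically smaller than neontological ones, isometry is the null
hypothesis, and low power therefore manufactures *false isometry* — a
Type II-like error that makes allometric growth look isometric in
small-sample studies.

## The model and statistics

For a trait $y$ and reference size $L$ (both linear measurements in mm),
the allometric model is

$$\log_{10} y = a + b \log_{10} L,$$

with $b = 1$ isometry, $b > 1$ positive and $b < 1$ negative allometry.
Slopes are fitted by OLS ($b = S_{xy}/S_{xx}$) and SMA
($b = \mathrm{sign}(r)\, s_y / s_x$, with the standardized-major-axis CI
$b(\sqrt{B+1} \mp \sqrt{B})$, $B = F_{0.95;1,n-2}(1-r^2)/(n-2)$). A trait is
classified by whether the 95% CI of $b$ lies entirely above 1, entirely
below 1, or includes 1; isometric results split into *hard* vs *soft*
isometry by the slope-vs-1 p-value (soft = plausibly a power artefact).

Four subsampling schemes (random, even-length binned, even-occupancy
binned, adult-biased) are swept over subsample size $n$ with replicated
draws; the *minimum sample size* of a trait is the first $n$ at which 95%
of replicates reproduce the full-sample category. Across traits, minimum
sample size follows an inverse hyperbola of slope,

$$y = \frac{m}{|x - b|} \qquad\text{or}\qquad y = \frac{m}{|x - b|} + c,$$

whose vertical asymptote $b$ sits just below 1; the two models are compared
by AIC and Akaike weights. A literature-survey module summarizes published
sample-size distributions per group (vertebrate/invertebrate,
extant/extinct) and compares them with two-sample Kolmogorov-Smirnov tests.
A synthetic-data generator (log-linear growth with Gaussian log-residuals,
plus a log-normal survey simulator) makes the whole pipeline testable with
known ground truth.

## Worked example

```r
library(allopower)

# a 108-specimen synthetic cranial series with published allometric structure
tab <- simulate_dataset(alligator_like_spec(), 108, seed = 1)

res <- regress_all(tab, "OLS")
head(report_regression(res), 3)
#>   variable    R2 intercept slope   lCI   uCI trend  sig
#> 1    var23 0.911   -0.3831 0.642 0.604 0.681     - ****
#> 2    var10 0.964   -0.0524 0.655 0.631 0.680     - ****
#> 3     var9 0.981   -0.0544 0.715 0.696 0.735     - ****

# subsample the strongly positive trait var7 and find its minimum sample size
pc <- run_sweep(tab, "var7", "OLS", "random", n_range = 3:40, reps = 200,
                seed = 2)
min_sample_for_agreement(pc, "positive")
#> <min_sample> var7 / OLS / random (truth positive): 9

head(error_rates(pc, "positive"), 4)
#>   n false_allometry false_isometry sign_error
#> 1 3               0          0.880      0.005
#> 2 4               0          0.715      0.000
#> 3 5               0          0.430      0.000
#> 4 6               0          0.345      0.000
```

Reading this: `var7` grows with slope ≈ 1.13, and nine specimens drawn at
random already suffice for 95% of replicates to call it positively
allometric; at $n = 3$–6, however, most replicates wrongly conclude
isometry (`false_isometry` 0.88 down to 0.35) — exactly the small-sample
failure mode the package quantifies.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data and
write their tables under `results/` (pass a seed as the first argument):

1. `01_simulate_data.R` — generate the measurement series and survey table
2. `02_full_sample_regression.R` — full-sample OLS/SMA fits and categories
3. `03_subsampling_power.R` — four-scheme sweeps, minimum-n, error rates
4. `04_scaling_law.R` — hyperbolic minimum-n-vs-slope fits with AIC weights
5. `05_survey_analysis.R` — survey group summaries and KS comparisons

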