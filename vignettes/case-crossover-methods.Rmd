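---
title: "Methods: time-stratified case-crossover estimation for air pollution and ED visits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-stratified case-crossover estimation for air pollution and ED visits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(aircrossover)
```

## The design and the model

The package estimates short-term associations between daily ambient air
pollution and daily counts of emergency department (ED) visits using a
time-stratified case-crossover design. Each calendar day is assigned to a
cluster keyed by its year, month and day of week, so a Tuesday in June 2010
is compared only with the other Tuesdays of June 2010. Clusters therefore
contain 4 or 5 days, never cross month boundaries, and — because referents
are so close in time — remove slow trends, seasonality, day-of-week
patterns and all time-invariant confounding (demography, socioeconomics,
comorbidity) by construction.

Within this design, daily counts $y_i$ are modelled as Poisson with
log-rate

$$\log \mu_i = \alpha_{C(i)} + \beta_1 x_i + s_3(\text{temp}_i) + s_3(\text{RH}_i),$$

where $x_i$ is the exposure of interest measured $\ell$ days before day
$i$ (a single-day lag, $\ell = 0,\dots,14$), and $s_3(\cdot)$ are natural
cubic splines with 3 degrees of freedom in same-lag temperature and
relative humidity. The cluster intercepts $\alpha_C$ are nuisance
parameters — one per year-month-weekday cell, about a thousand over a
decade-long study — and are eliminated by conditioning on each cluster's
total count. Conditionally on $N_C = \sum_{i \in C} y_i$, the counts are
multinomial with cell probabilities
$\pi_i = e^{\eta_i} / \sum_{j \in C} e^{\eta_j}$, giving the conditional
log-likelihood

$$\ell(\beta) = \sum_i y_i \eta_i - \sum_C N_C \log \sum_{j \in C} e^{\eta_j},
\qquad \eta_i = \beta^{\mathsf T} x_i .$$

This objective is concave (it is a sum of multinomial log-likelihoods),
its maximiser coincides exactly with the fixed-effects Poisson estimate in
which every cluster gets its own intercept, and it never estimates the
$\alpha_C$ themselves. The test suite verifies the equivalence on an
exhaustive enumeration of small two-cluster designs and on random larger
ones.

Overdispersion is absorbed quasi-Poisson style: the dispersion
$\hat\phi = \sum_i (y_i - \hat\mu_i)^2/\hat\mu_i \,/\, (n - k - p)$ is the
Pearson statistic over the residual degrees of freedom, where $\hat\mu_i =
N_C \hat\pi_i$ are the conditional fitted means, $n$ counts days in
clusters with a positive total, $k$ counts those clusters and $p$ the
regression parameters. Subtracting $k$ mirrors the fixed-effects
equivalence — each informative cluster absorbs one intercept — and makes
the estimate agree exactly with `glm(..., family = quasipoisson)` plus
cluster indicators, which the tests check. Standard errors are
$\sqrt{\hat\phi}$ times the model-based ones from the inverse observed
information.

Effect sizes are reported as relative risks per interquartile-range (IQR)
increase, $\mathrm{RR} = e^{\beta_1 \cdot \mathrm{IQR}}$, with Wald
intervals $e^{(\beta_1 \pm z_{0.975}\,\mathrm{SE})\cdot \mathrm{IQR}}$ at
the two-tailed 0.05 level. By default the IQR is computed once from the
full daily series, so all strata of one exposure share a common increment;
`iqr_scope = "per_stratum"` switches to per-model IQRs.

## Exposure metrics and the composite indices

Hourly station records are averaged to station-days (a day is valid when
at least 75% of its 24 hours report — 18 hours — configurable), then
averaged without weights over reporting stations into a city-wide daily
value. Ozone additionally gets a daily maximum 8-hour metric: the maximum
over forward-looking 8-hour running means whose start hour lies in the
day. Two window policies are provided: the default considers only windows
wholly inside the day (start hours 0–16); `"spillover"` allows start hours
up to 23, borrowing the first 7 hours of the following day. Negative
measured concentrations (possible near the detection limit after
instrument calibration) are retained and pass through means and the index
formula unmodified.

The Air Quality Health Index combines three pollutants:

$$\mathrm{AQHI} = \frac{1000}{10.4}\left(e^{0.000537\,\mathrm{O_3}} +
e^{0.000871\,\mathrm{NO_2}} + e^{0.000487\,\mathrm{PM_{2.5}}} - 3\right),$$

with O3 and NO2 in ppb and PM2.5 in µg/m³. The constants are frozen; the
variant AQHI-x feeds the daily maximum 8-hour ozone into the same formula.
Models always consume the continuous index; the public 1–10+ integer
scale is provided for presentation only. Over day-to-day variation of
roughly one IQR around the long-run means the index is nearly linear (the
tests bound the deviation from its first-order expansion by 0.05 index
units over mean ± IQR boxes), so IQR-scaled RRs on the index have a
stable interpretation. Evaluated at long-run mean inputs of 23.5 ppb O3,
16.1 ppb NO2 and 8.9 µg/m³ PM2.5 the formula gives 2.997, i.e. 3.0 at
reporting precision.

The interquartile range uses linear interpolation between order statistics
(R's type-7 quantile). The convention is pinned and tested because the RR
scale depends on it; it requires at least 4 non-missing values, which any
daily series of analytic interest satisfies.

## Strata, outcome blocks and the model grid

Analyses are stratified 18 ways: sex (all/male/female) crossed with either
age group (0–10, 11–60, >60 years) or season (cold: October–March; warm:
April–September), never both. The top age group is taken as age ≥ 61
("greater than 60"); changing it to ≥ 60 is a one-line switch in
`age_group_of()`. Season strata restrict the analysis *days* — cases and
referents alike — which is self-consistent because clusters are
month-bound and months are wholly cold or warm.

Outcomes are ICD-10 chapter VI (G00–G99) visits, grouped into the eleven
standard diagnostic blocks; codes in undefined gaps (G15–G19, …) are
excluded. Within the episodic and paroxysmal block (G40–G47), sub-codes
are tagged (epilepsy G40/G41, migraine G43, other headaches G44,
ischaemic attacks G45, sleep disorders G47) for descriptive tables.

The full grid crosses 8 exposures (CO, NO2, SO2, PM2.5, O3, O3H8, AQHI,
AQHI-x) × 15 lags (0–14 days) × 18 strata = 2,160 models per outcome
block. Models that fail (non-convergence, exposure constant within every
cluster) are recorded as non-converged rows, never dropped. No
multiple-testing adjustment is applied on the primary path — each model is
its own two-tailed 0.05 test, and the count of significantly *positive*
associations (lower CI bound above 1) is the summary statistic, arranged
as strata × exposures, exposures × lags and strata × lags arrays. A
Benjamini–Hochberg column is available as an off-by-default sensitivity
aid.

## The synthetic-data generator

No individual-level ED data can be redistributed, so the package carries a
generator that emulates the statistical structure the estimator assumes,
and the validation suite runs entirely on it.

*Exposures.* Each pollutant is a seasonal sinusoid (period 365.25 d,
peak near early July) around its long-run mean plus stationary AR(1)
noise, clipped at a configurable floor (default 0; set `-Inf` to disable,
or a small negative floor to mimic near-detection-limit readings). The
default means (CO 0.3 ppm, NO2 16.1 ppb, SO2 1.4 ppb, O3 23.5 ppb, PM2.5
8.9 µg/m³) are typical long-run urban levels in a large Canadian city, and
the amplitude/autocorrelation/noise settings are chosen once so the
simulated IQRs land near realistic values (about 0.1 ppm for CO, 8–9 ppb
for NO2). The 8-hour ozone metric is simulated as 1.86 × O3 plus noise,
reproducing the observed ratio of the two ozone metrics' long-run means,
and both indices are computed from the simulated components with the real
formula. Temperature has a 12 °C annual amplitude around 9.5 °C with AR(1)
day-to-day persistence; humidity is nearly aseasonal around 70%.

*Counts.* The whole-population daily count is negative binomial with mean
$\mu_t$ and variance $\kappa \mu_t$ (exactly Poisson at $\kappa = 1$;
the quasi-Poisson estimator only assumes the variance inflation, and the
negative binomial is the concrete law chosen to realise it). The log mean
is the log baseline (default 32.7 visits/day, a realistic large-city ED
volume for this diagnostic chapter) plus an i.i.d. normal intercept per
year-month-weekday cluster (sd 0.1 by default — the estimator must be
insensitive to these, which is itself a test), plus the configured lagged
exposure effects, plus a quadratic in standardised temperature and
humidity. The quadratic is deliberately smooth and spline-capturable, so
weather confounding is active but controllable. The default
overdispersion of 1.5 is a moderate, realistic inflation for daily ED
counts; it is a simulation choice, not an empirical estimate.

*Records.* Daily counts are disaggregated into individual visit records by
sampling sex, age group and diagnostic code independently from category
weights that follow the observed demographic and diagnostic mix of
nervous-system ED visits (59.5% female; the episodic and paroxysmal block
about 64% of visits, migraine about 39% of those). Because attributes are
sampled independently of the day's rate, every sub-stratum inherits the
same true exposure slope — which is what the stratified estimator should
recover.

What the generator does *not* emulate: station-level spatial structure and
inter-station correlation (it generates the city-wide series directly),
hourly resolution (daily suffices to exercise the estimator; the hourly
aggregation operations are tested on small hand-built hourly tables),
sex- or age-specific effect modification, and exposure measurement error.
Passing tests on synthetic data therefore demonstrate the estimator's
correctness under the stated model, not robustness to these additional
features of real data.

## Numerical choices

- **Optimiser.** Newton iteration with analytic gradient and Hessian,
  step-halving, starting at $\beta = 0$; the conditional objective is
  concave so the start is benign. Within-cluster log-sum-exp terms are
  stabilised by subtracting the cluster maximum.
- **Convergence.** Gradient max-norm below 1e-8 on an internally
  standardised covariate scale (columns scaled to unit variance, estimates
  transformed back), so the criterion is invariant to exposure units.
- **Identifiability.** A covariate constant within every informative
  cluster is an explicit error, never a silent zero. Days in clusters with
  zero total counts are retained but contribute nothing to the likelihood.
- **Splines.** Knots at the fitted subset's own quantiles (interior knots
  at the 33.3rd/66.7th percentiles for 3 df, boundary knots at min/max),
  recomputed per model — including per season stratum.
- **Dispersion df.** $n - k - p$ as derived above; with this choice the
  dispersion matches the fixed-effects quasi-Poisson `glm` exactly.

## Validation problem sizes

The test suite validates the estimator by simulation at sizes chosen to
make Monte-Carlo error small while keeping the default run quick: slope
recovery and 95% CI coverage over 500 replicates of 1,000-day studies
(coverage must fall in [92%, 98%]); null calibration of the
positive-significance rate over 500 replicates of 600-day studies (about
2.5% under the two-tailed 5% test); dispersion calibration over 100
replicates each of Poisson and inflation-2 data at 500 days; generator
moment checks at 20,000 days. The full 4,292-day, 2,160-model study scale
runs the same code paths and is exercised directly for the calendar and
grid-arithmetic checks.

## Known limitations

- Single-pollutant, single-lag models only: no distributed-lag nonlinear
  models, multi-pollutant models, random-effects or Bayesian variants, and
  no robust/sandwich alternative to quasi-Poisson scaling.
- Wald intervals with the normal quantile; with ~1,000 informative
  clusters the difference from a t-based interval is negligible, but very
  short series would be better served by the t.
- The AQHI-x long-run mean cannot be reproduced by evaluating the formula
  at the long-run means of its inputs: the index is convex in its inputs,
  so the mean of daily index values exceeds the index of mean inputs
  (Jensen's inequality), and the size of that gap depends on the joint
  day-to-day distribution. The package therefore anchors numeric checks on
  the AQHI, whose day-level nonlinearity is negligible at its observed
  levels.
- Multiplicity across the 2,160-model grid is reported, not corrected;
  the per-model 2.5% positive flag rate under the null is itself a tested
  property, and the optional FDR column quantifies the adjustment when
  wanted.
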