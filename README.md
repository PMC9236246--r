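# aircrossover

Time-stratified case-crossover analysis of ambient air pollution and daily
emergency department (ED) visit counts, for environmental epidemiologists
studying short-term exposure–response at the city scale.

## What it does

The package estimates the association between a lagged daily exposure
(one of CO, NO2, SO2, PM2.5, O3, the daily maximum 8-hour ozone O3H8, or
the composite indices AQHI and AQHI-x) and daily counts of ED visits for
nervous-system diagnoses (ICD-10 G00–G99 and its diagnostic blocks).
Calendar days are grouped into year × month × day-of-week clusters of 4–5
days; conditioning on each cluster's total visit count eliminates the
cluster intercepts and yields the conditional (multinomial) Poisson
log-likelihood

    ℓ(β) = Σᵢ yᵢ ηᵢ − Σ_C N_C log Σ_{j∈C} exp(ηⱼ),   ηᵢ = βᵀxᵢ,

with xᵢ the lagged exposure plus natural cubic splines (3 df) of same-lag
temperature and relative humidity. The likelihood is maximised by Newton
iteration; overdispersion is absorbed quasi-Poisson style (Pearson
χ²/df), and the estimate coincides exactly with fixed-effects Poisson
regression with one indicator per cluster. Effects are reported as
relative risks per interquartile-range (IQR) increase,
RR = exp(β·IQR), with 95% Wald intervals.

The Canadian Air Quality Health Index is built in:

    AQHI = 1000/10.4 × (e^(0.000537·O3) + e^(0.000871·NO2) + e^(0.000487·PM2.5) − 3)

and the full analysis grid — 8 exposures × 15 lags (0–14 days) × 18
strata (sex crossed with age group or season) = 2,160 models per outcome
block — can be enumerated, fitted and summarised as arrays of
significant-positive association counts.

Because individual-level ED records cannot be redistributed, the package
ships a synthetic-data generator producing seasonal, autocorrelated
exposure series and overdispersed visit counts with known effects, on
which the whole pipeline is validated (parameter recovery, CI coverage,
null calibration, dispersion calibration).

## Worked example

Simulate two years-plus of data with a true CO effect at lag 1 of 0.19
per ppm (RR 1.019 per 0.1 ppm), build the count series, and fit:

```r
library(aircrossover)

params <- sim_params(
  n_days = 2000, seed = 1,
  true_effects = tibble::tibble(exposure = "CO", lag = 1, slope = 0.19)
)
ds <- simulate_dataset(params)
ds
#> Synthetic case-crossover dataset: 2000 study days, 73347 visits, 2001 exposure days

counts <- build_counts(ds$visits,
                       period = c(params$start_date,
                                  params$start_date + params$n_days - 1))
model_data <- attach_lags(
  dplyr::filter(counts, stratum_id == "all|all|all", block == "G40-G47"),
  ds$exposures, exposure = "CO", lag = 1
)
fit <- fit_model(model_data)
fit
#> Conditional quasi-Poisson fit: 2000 days in 462 clusters; converged in 4 iterations
#>   exposure beta = 0.1984  se = 0.09386  dispersion = 1.291
```

The exposure coefficient (0.198 per ppm) recovers the planted slope of
0.19 within its standard error, and the dispersion (1.29) reflects the
generator's variance inflation of 1.5 diluted by binomial thinning to the
G40–G47 block. Scaling to the CO interquartile range:

```r
iqr <- compute_iqr(ds$exposures$CO)   # 0.101 ppm
rr_from_fit(fit, delta = iqr)
#> # A tibble: 1 × 5
#>      rr lower upper delta level
#>   <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1  1.02  1.00  1.04 0.101  0.95
```

i.e. a 2% increase in episodic-and-paroxysmal-disorder visits per IQR
increase in CO, with the interval just excluding 1. A reduced grid shows
the summary machinery (the true effect sits in the CO/lag-1 column; its
neighbours echo it through exposure autocorrelation):

```r
specs <- enumerate_models(exposures = c("CO", "NO2"), lags = 0:2,
                          strata = enumerate_strata()[1:3, ],
                          blocks = "G40-G47")
res <- run_grid(specs, counts, ds$exposures)
significance_counts(res)
#> Significant positive associations: 3 models
#> Exposure x lag counts:
#>     0 1 2
#> CO  1 1 0
#> NO2 0 1 0
```

See `vignettes/case-crossover-methods.Rmd` for the model, its
assumptions, the generator's design and the numerical conventions.

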