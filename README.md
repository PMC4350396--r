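# budbreakr

Process-based modelling of spring bud break in Scots pine (*Pinus
sylvestris* L.) at high latitudes, for forest phenologists and
dendroecologists who want a tested, reproducible version of the classic
chilling–forcing analysis chain: predict bud break from daily
temperatures, derive observed dates from weekly shoot-growth
measurements, calibrate the models by minimizing RMSE, reconstruct
century-long bud-break series from station temperature records, and test
the reconstructed series for linear trends under autoregressive errors.

## The models

Both model structures accumulate forcing units (FU) until a critical sum
`fu_crit`; the day it is reached is the predicted bud-break date. The
daily forcing rate is a sigmoid in mean daily temperature `T` (°C):

    m_frc(T) = 0                          for T ≤ 0
    m_frc(T) = a / (1 + exp(−b (T − c)))  for T > 0

* **Model DL** (day-length proxy) releases forcing on a fixed day of
  year.
* **Model IA** (sequential chilling) first accumulates chilling units
  (CU) from the rest-period start (September 1) under a triangular
  response — zero outside (−3.4, 10.4] °C, peaking near 3.5 °C — and
  releases forcing the day after the chilling requirement `cu_crit` is
  met.

An observed plot bud-break date is the earliest day on which more than
half of the sample trees have elongated ≥ 1 mm *and* the plot-mean
increment is ≥ 1 % of the season total, with per-tree linear
interpolation between weekly visits. Calibration is a bounded,
seed-deterministic genetic algorithm; reconstruction omits years with
temperature gaps in the consumed window; the trend model
`doy = β0 + β1·year + AR error` is estimated both by maximum likelihood
and by OLS, with `β1 × horizon` giving the implied change in days.

## Worked example

A fully synthetic run — subarctic climate with a known true model, weekly
noisy measurements, then the whole chain:

```r
library(budbreakr)

climate <- simulate_temperature(climate_params(years = 1950:2010,
                                               rng_seed = 42,
                                               trend_c_per_decade = 0.2))
truth <- model_spec("DL", forcing_params(22, 0.5, 8, 150),
                    forcing_start_doy = 80)
sim <- simulate_observations(climate,
         obs_gen_params(truth, noise_sd_mm = 0.3, jitter_days = 1,
                        rng_seed = 42), 2001:2009)
obs <- as_observation_table(lapply(2001:2009, function(y)
  derive_budbreak_date(
    sim$measurements[format(sim$measurements$date, "%Y") == y, ])))

fit <- calibrate_model("DL", climate, obs,
                       config = ga_config(population_size = 100,
                                          max_generations = 200,
                                          rng_seed = 42))
fit
#> <calibration_result> kind DL, RMSE 0.333 days over 9 observation(s), 59 generation(s)
#> <model_spec> kind DL
#>   forcing: a=26.66 b=0.5691 c=7.843 fu_crit=189.9
#>   forcing starts on day of year 32

rec <- reconstruct_budbreak(climate, NULL, fit$model, 1951:2010)
set.seed(42)
fit_trend(rec, ar_order = "auto", horizon_years = 100)
#> <trend_result> n = 60 years, AR order 0
#>   ML : slope -0.0795 d/yr (se 0.0331, p 0.0196)
#>   OLS: slope -0.0795 d/yr (se 0.0331, p 0.0196)
#>   lag-1 autocorrelation: DW 1.943 (perm p 0.8080)
#>   implied change over 100 years: -7.95 days
```

The calibrated model reproduces the derived observation dates to a third
of a day RMSE (dates, not parameters, are the identifiable quantity),
and the reconstruction picks up the +2 °C/century warming built into the
synthetic climate as an advance of about 8 days per century in bud
break, with no significant residual autocorrelation.

The package also ships the fifteen observed plot-year bud-break dates
from the two study sites; `observation_stats(observed_budbreak())`
summarizes them (largest within-plot range: 16 days).

## Package layout

* `R/temperature.R` — daily/hourly series, CSV I/O, offsets
* `R/phenology.R` — forcing and chilling rates, model structures,
  prediction, accumulation curves
* `R/observations.R` — growth measurements, detection rule, summary
  statistics
* `R/calibration.R` — bounds, GA, RMSE objective
* `R/trend.R` — reconstruction, AR-error trend, autocorrelation test
* `R/synthetic.R` — climate and growth-measurement generators
* `R/pipeline.R` — `run_pipeline()`: derive → calibrate → reconstruct →
  trend with a run manifest

See `vignettes/budbreak-modelling.Rmd` for the scientific account of the
models, conventions and limitations.
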