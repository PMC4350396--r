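---
title: "Modelling and reconstructing bud break of Scots pine at high latitudes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and reconstructing bud break of Scots pine at high latitudes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(budbreakr)
```

## The problem

Bud break — the date a pine's leader-shoot bud begins measurable
elongation — is a classic bioindicator of spring climate. At the northern
tree line the growing season is short, so Scots pine flushes as early as
day length and temperature allow, and the timing of flushing responds
strongly to spring temperature. `budbreakr` implements a complete analysis
chain for this system: process-based bud-break models, derivation of
observed bud-break dates from weekly growth measurements, calibration of
the models to those observations, reconstruction of century-long bud-break
series from daily station temperature records, and trend analysis of the
reconstructed series under autoregressive errors. A synthetic-data module
generates subarctic temperature records and growth measurements with a
known true model, so the whole chain is testable without access to any
meteorological archive.

## The process models

Both model structures accumulate *forcing units* (FU) until a critical sum
`fu_crit` is reached; the day that happens is the predicted bud-break
date. The daily forcing rate is a sigmoid in mean daily air temperature
$T$ (°C):

$$
m_{frc}(T) =
\begin{cases}
0, & T \le 0\,°C \\
\dfrac{a}{1 + e^{-b\,(T - c)}}, & T > 0\,°C
\end{cases}
$$

with asymptote $a$ (FU day⁻¹), slope $b$ (°C⁻¹), and inflection
temperature $c$ (°C). The widely used multi-species boreal defaults
($a = 28.361$, $b = 0.185$, $c = 18.431$) serve as starting values for
calibration.

What differs between the two structures is when forcing is released:

* **Model DL** (day-length proxy): forcing accumulates from a fixed day
  of year, that day inclusive. Day length at a fixed latitude is a pure
  function of the calendar, so a fixed date stands in for a photoperiod
  threshold without any solar geometry.
* **Model IA** (sequential chilling): the bud must first accumulate
  *chilling units* (CU) from the rest-period start (September 1 by
  convention) until the chilling requirement `cu_crit` is met — the
  competence date — and forcing accumulates from the **following** day,
  so no day is double-counted. The daily chilling rate is triangular:

$$
M_{chl}(T) =
\begin{cases}
0, & T \le -3.4\,°C\\
0.159\,T + 0.506, & -3.4 < T \le 3.5\,°C\\
-0.159\,T + 1.621, & 3.5 < T \le 10.4\,°C\\
0, & T > 10.4\,°C
\end{cases}
$$

### Numerical conventions

A handful of small decisions matter for exact reproducibility, so they
are fixed and documented here:

* **Clamping**: the published coefficients of the rising chilling branch
  are rounded, which makes the rate slightly negative for
  $-3.4 < T \lesssim -3.18$ °C (e.g. $0.159 \cdot (-3.4) + 0.506 =
  -0.0346$). Chilling units cannot be negative, so the rate is clamped at
  zero.
* **Branch tie**: at exactly $T = 3.5$ °C the two linear branches
  disagree slightly (1.0625 vs 1.0645); the printed inequalities put 3.5
  in the lower branch, which is what `chilling_rate(3.5)` returns.
* **Day granularity**: accumulation is per calendar day with no
  sub-daily interpolation, matching daily driver data. The release day
  itself contributes forcing (inclusive start); the predicted date is the
  first day the cumulative sum meets the criterion.
* **Window**: accumulation ends June 30. Observed bud break at these
  latitudes falls in May, so June 30 leaves a wide margin; a model that
  has not met `fu_crit` by then returns an explicit "not reached" rather
  than an error.
* **Rest-start anchoring**: a rest-start month-day from July onward
  refers to the autumn *before* the bud-break spring (September 1 of year
  $Y-1$ for bud break in year $Y$); a month-day in January–June refers to
  year $Y$ itself. This keeps the sequential model well-defined for
  unconventional rest starts and makes `cu_crit = 0` exactly equivalent
  to a fixed-date model released on the same day.
* **Leap years**: calendar dates are primary; day of year is computed
  from the actual calendar, so February 29 counts. Cross-year summaries
  of observation ranges therefore align dates by month-day position
  rather than raw day of year.

## From growth measurements to observed dates

Field observations are weekly cumulative leader-shoot lengths per tree.
The plot-level bud-break date is the earliest day on which **both** hold:

1. more than half of the sample trees (strict inequality, so 5 of 10
   does not qualify) have elongated at least 1 mm, and
2. the plot-mean increment is at least 1 % of the plot-mean season total
   (the season total of a tree being its final measurement of the
   season).

Because the criteria are usually crossed between weekly visits, each
tree's series is linearly interpolated to daily resolution *first* and
the criteria are evaluated on the daily grid; the result is reported at
whole-day resolution. Edge cases are explicit: criteria already satisfied
at the first evaluable day are flagged `left_censored`, criteria never
satisfied give `not_detected` rather than a date.

`observed_budbreak()` ships the fifteen observed plot-year dates from the
two study sites (five plots, three seasons each); `observation_stats()`
reproduces their summary statistics, e.g. the largest within-plot range
of 16 days:

```{r}
observation_stats(observed_budbreak())$per_plot
```

## Calibration

`calibrate_model()` minimizes the RMSE (in days) between predicted and
observed dates over a bounded parameter space: `fu_crit` in [0, 250],
`a` in [15, 40], `b` in [0.01, 1.0], `c` in [5, 30], plus `cu_crit` in
[0, 120] (IA, rest start fixed at September 1) or the release day of
year in [1, 151] (DL). All observations of a site are pooled into one
objective. A year whose forcing requirement is never met is scored as
June 30, which keeps the objective finite early in the search.

The optimizer is a generational genetic algorithm. The published
protocol fixes convergence tolerance 0.0001, mutation rate 0.1 and
population 250, but stops on 60 wall-clock seconds without improvement,
which is irreproducible; we replace it with a deterministic patience of
50 stalled generations (and a hard cap of 500), seeded through
`rng_seed`. The GA mechanics themselves are not prescribed by any
convention, so common defaults are used and exposed: tournament
selection of size 3, uniform crossover with rate 0.7, per-gene Gaussian
mutation with SD equal to 10 % of the bound width, bound clipping,
elitism of 1, and integer rounding for the date-valued gene. The default
starting values are seeded into the initial population, so the fit can
never be worse than the default model. Ties in RMSE are broken toward
smaller `fu_crit`, then smaller `cu_crit` (parsimony). Because the
objective is a function of whole-day dates, many parameter sets fit
equally well: the contract of calibration is date fit, not parameter
identifiability.

## Reconstruction and trend

A short on-site record is tied to a century-long station record by an
additive offset — the mean site-minus-station difference over April–May
of the calibration years (`compute_offset()`; arbitrary month sets are
supported for logger-to-station calibration, since it is not documented
whether that step used all months or only the growing season). The
offset is applied to *every* day of the station record, preserving the
shape of the series while shifting its level.

`reconstruct_budbreak()` then predicts one date per year. A year is
omitted when any daily value in April 1 – May 31 is missing, or when a
gap falls inside the window the model actually consumed — for the
sequential model this includes the previous autumn and winter, which is
deliberately stricter than the April–May screen alone. Omissions are
recorded with reasons rather than silently dropped.

`fit_trend()` estimates `doy = β₀ + β₁·year + ε` with AR errors along
two paths, mirroring the classic ML/OLS contrast of time-series
regression packages: maximum likelihood of the joint AR-error regression
(generalized least squares with an AR correlation structure indexed by
calendar year, so omitted years enter as genuine gaps in the correlation
structure), and ordinary least squares of the plain regression. ML-type
estimators of this model are known to attribute more variance to the
residual process and OLS less, so borderline trends can be significant
under one and not the other; both inference sets are always reported,
with two-sided p-values and no significance stars. The AR order defaults
to 1, with an AIC-based automatic choice over orders 0–2, since the
order used by the original station-record analyses is not documented.
The residual lag-1 autocorrelation check is a Durbin–Watson-style
statistic with a permutation p-value — a deliberate stand-in, since the
exact test of the original time-series procedure is also undocumented.
`implied_change()` converts a slope to days over a horizon by plain
multiplication, e.g. −0.028 d yr⁻¹ over 107 years ≈ 3 days of advance.

## The synthetic generator

`simulate_temperature()` builds daily series as annual cosine cycle +
linear trend + AR(1) anomalies:
mean −1 °C, seasonal amplitude 14 °C, warmest day near day-of-year 200,
anomaly autocorrelation 0.6 and marginal SD 3 °C by default — a
plausible subarctic inland preset, chosen once for realism and not a
claim about any real station. Gap ranges can be blanked to emulate
missing archive stretches, and a trend in °C/decade emulates century
warming. `simulate_observations()` draws true bud-break dates from a
known model, then grows each tree along a logistic curve to its season
total (reaching ~1.8 % of the total on the onset day itself, so the
1 mm / 1 % criteria hold from day one), jitters per-tree onsets by up to
±2 days, samples weekly by default, and adds measurement noise with a
running maximum to keep cumulative lengths monotone. The paper-level
analyses only constrain the *onset*, so any monotone post-onset curve
would do; the logistic is chosen for realism.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data — includes: daily minimum/maximum structure
(models are driven by daily means only), solar radiation, soil
temperature, ground frost and snow melt; station relocations and
inhomogeneities; and observer effects in the field measurements, such as
the real staggered flushing that makes slow warm-ups hard for the
criteria-based definition.

## Problem sizes and verification

The test suite checks each stage against independent oracles coded as
explicit day loops: brute-force accumulators for both model kinds on 100
random synthetic series, a brute-force daily evaluator of the plot
criteria, closed-form constant-temperature predictions, and full
recovery loops (simulate → derive → calibrate) with noise-free and noisy
weekly sampling. Calibration recovery uses 9 synthetic years with a
population of 100 and up to 200 generations across 20 seeds; trend
checks use 100-year series with 200 replicates for slope recovery
(AR(1) φ = 0.3, σ = 3 d, slope −0.04 d yr⁻¹) and 200 white-noise
replicates for the size of the ML slope test. These sizes were chosen to
make sampling noise small relative to the tolerances being checked.

## Known limitations

* Only the two model structures that performed best in this system are
  implemented; parallel and competence-function variants are out of
  scope.
* The GA explores a date-quantized objective, so different seeds can
  settle on different parameter sets of equal date fit; report and
  compare predicted dates, not parameters.
* The ML slope test is mildly anti-conservative under strongly
  autocorrelated errors in century-length samples (empirical size ≈ 7 %
  at φ = 0.3, n = 100); under white noise it is well calibrated.
* Reconstructions inherit the level of the offset adjustment: series
  built from different stations are comparable in trend and variation,
  not in absolute level.
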