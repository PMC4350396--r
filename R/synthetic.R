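#' Synthetic subarctic climate parameters
#'
#' Parameters of the daily temperature generator: an annual cosine cycle
#' plus AR(1) daily anomalies and an optional linear warming trend. The
#' defaults describe a subarctic inland climate plausible for the
#' northern-Fennoscandia study region: annual mean -1 degC, seasonal
#' amplitude 14 degC, warmest day around day of year 200, anomaly lag-1
#' autocorrelation 0.6, marginal anomaly SD 3 degC, no trend. They are
#' presets for testing, not claims about any real station.
#'
#' @param mean_c annual mean temperature (degC).
#' @param amplitude_c seasonal half-range (degC).
#' @param phase_doy day of year of the warmest day.
#' @param ar1 lag-1 autocorrelation of daily anomalies, `|ar1| < 1`.
#' @param anomaly_sd marginal standard deviation of anomalies (degC).
#' @param trend_c_per_decade linear warming applied across the record.
#' @param years integer vector of calendar years to generate.
#' @param gaps optional list of `c(from, to)` date strings blanked to
#'   gaps.
#' @param rng_seed integer seed.
#' @export
climate_params <- function(mean_c = -1, amplitude_c = 14, phase_doy = 200,
                           ar1 = 0.6, anomaly_sd = 3,
                           trend_c_per_decade = 0, years,
                           gaps = NULL, rng_seed = NULL) {
  stopifnot(amplitude_c >= 0, abs(ar1) < 1, anomaly_sd >= 0,
            length(years) >= 1)
  structure(list(mean_c = mean_c, amplitude_c = amplitude_c,
                 phase_doy = phase_doy, ar1 = ar1, anomaly_sd = anomaly_sd,
                 trend_c_per_decade = trend_c_per_decade,
                 years = as.integer(years), gaps = gaps,
                 rng_seed = rng_seed),
            class = "climate_params")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a daily temperature series
#'
#' Daily value = mean + seasonal cosine + trend + AR(1) anomaly, where the
#' anomaly innovations are scaled so `anomaly_sd` is the marginal SD.
#' Requested gap ranges are blanked afterwards. The generator is a pure
#' function of its parameter object, seed included.
#'
#' @param p a [climate_params] object.
#' @param site_id site label of the returned series.
#' @return a [daily_temps] object from January 1 of the first year to
#'   December 31 of the last.
#' @examples
#' s <- simulate_temperature(climate_params(years = 2000:2002, rng_seed = 1))
#' @export
simulate_temperature <- function(p, site_id = "synthetic") {
  stopifnot(inherits(p, "climate_params"))
  dates <- seq(as.Date(sprintf("%d-01-01", min(p$years))),
               as.Date(sprintf("%d-12-31", max(p$years))), by = "day")
  doy <- as.integer(strftime(dates, "%j"))
  n <- length(dates)
  seasonal <- p$mean_c +
    p$amplitude_c * cos(2 * pi * (doy - p$phase_doy) / 365.25)
  elapsed <- as.numeric(dates - dates[1]) / 365.25
  trend <- p$trend_c_per_decade * elapsed / 10
  anom <- with_seed(p$rng_seed, {
    if (p$anomaly_sd == 0) {
      numeric(n)
    } else {
      innov_sd <- p$anomaly_sd * sqrt(1 - p$ar1^2)
      e <- stats::rnorm(n, 0, innov_sd)
      a <- numeric(n)
      a[1] <- stats::rnorm(1, 0, p$anomaly_sd)
      for (i in 2:n) a[i] <- p$ar1 * a[i - 1] + e[i]
      a
    }
  })
  v <- seasonal + trend + anom
  v <- pmin(pmax(v, -60), 45)  # keep inside the sanity window
  for (g in p$gaps) {
    g <- as.Date(g)
    v[dates >= g[1] & dates <= g[2]] <- NA_real_
  }
  daily_temps(dates, v, site_id = site_id)
}

#' Synthetic growth-observation parameters
#'
#' Parameters of the growth-measurement generator: the true bud-break
#' model driving onset dates, the sampling design (plots, trees per plot,
#' measurement interval), per-tree onset jitter, measurement noise, and
#' the distribution of season total growth.
#'
#' @param model the true [model_spec].
#' @param n_plots,n_trees number of plots and of trees per plot.
#' @param interval_days days between measurement visits (default 7,
#'   i.e. weekly).
#' @param noise_sd_mm SD of measurement noise added to positive lengths.
#' @param season_total_mean_mm,season_total_sd_mm per-tree season total
#'   growth distribution (mm).
#' @param jitter_days per-tree onset jitter, uniform on
#'   `-jitter_days..+jitter_days` whole days.
#' @param rng_seed integer seed.
#' @export
obs_gen_params <- function(model, n_plots = 1, n_trees = 10,
                           interval_days = 7, noise_sd_mm = 0.5,
                           season_total_mean_mm = 100,
                           season_total_sd_mm = 15, jitter_days = 2,
                           rng_seed = NULL) {
  stopifnot(inherits(model, "model_spec"), interval_days >= 1,
            noise_sd_mm >= 0, jitter_days >= 0)
  structure(list(model = model, n_plots = as.integer(n_plots),
                 n_trees = as.integer(n_trees),
                 interval_days = as.integer(interval_days),
                 noise_sd_mm = noise_sd_mm,
                 season_total_mean_mm = season_total_mean_mm,
                 season_total_sd_mm = season_total_sd_mm,
                 jitter_days = as.integer(jitter_days),
                 rng_seed = rng_seed),
            class = "obs_gen_params")
}

# logistic growth curve after onset: fraction of the season total reached
# d days after onset. At d = 0 about 1.8 % of the total (>= 1 mm for
# realistic totals), so the detection criteria hold on the onset day
# itself.
growth_fraction <- function(days_since_onset) {
  ifelse(days_since_onset < 0, 0,
         stats::plogis((days_since_onset - 20) / 5))
}

#' Simulate growth measurements around known bud-break dates
#'
#' For each requested year the true bud-break date comes from
#' [predict_budbreak()] under the true model; each tree then follows a
#' logistic cumulative growth curve to its season total, starting at the
#' true date plus a whole-day jitter, sampled at the measurement interval
#' with additive noise (monotonicity restored by a running maximum).
#' Measurement visits start three weeks before the earliest onset and
#' continue ten weeks after it. Years where the true model never reaches
#' the forcing requirement are skipped and flagged.
#'
#' @param temps a [daily_temps] covering all seasons' windows.
#' @param p an [obs_gen_params] object.
#' @param years integer vector of seasons to simulate.
#' @return list with `measurements` (data.frame
#'   `plot_id,tree_id,date,cum_length_mm`), `truth` (data.frame
#'   `plot_id,year,date,doy`), `skipped_years`.
#' @export
simulate_observations <- function(temps, p, years) {
  stopifnot(inherits(p, "obs_gen_params"))
  years <- as.integer(years)
  with_seed(p$rng_seed, {
    meas <- list()
    truth <- list()
    skipped <- integer(0)
    for (y in years) {
      pred <- predict_budbreak(temps, p$model, y)
      if (is.na(pred$date)) {
        skipped <- c(skipped, y)
        next
      }
      for (pl in seq_len(p$n_plots)) {
        plot_id <- sprintf("plot_%d", pl)
        onsets <- pred$date + if (p$jitter_days == 0) rep(0L, p$n_trees) else
          sample(seq(-p$jitter_days, p$jitter_days), p$n_trees, replace = TRUE)
        totals <- pmax(60, stats::rnorm(p$n_trees, p$season_total_mean_mm,
                                        p$season_total_sd_mm))
        visits <- seq(min(onsets) - 21, min(onsets) + 70,
                      by = p$interval_days)
        for (tr in seq_len(p$n_trees)) {
          len <- totals[tr] *
            growth_fraction(as.numeric(visits - onsets[tr]))
          if (p$noise_sd_mm > 0) {
            pos <- len > 0
            len[pos] <- len[pos] + stats::rnorm(sum(pos), 0, p$noise_sd_mm)
            len <- cummax(pmax(len, 0))
          }
          meas[[length(meas) + 1]] <- data.frame(
            plot_id = plot_id, tree_id = sprintf("%s_tree_%d", plot_id, tr),
            date = visits, cum_length_mm = len)
        }
        truth[[length(truth) + 1]] <- data.frame(
          plot_id = plot_id, year = y, date = pred$date, doy = pred$doy)
      }
    }
    list(measurements = do.call(rbind, meas),
         truth = do.call(rbind, truth),
         skipped_years = skipped)
  })
}
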