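# Fixture builders shared across test files.

constant_series <- function(temp, years = 2001, site_id = "const") {
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  daily_temps(dates, rep(temp, length(dates)), site_id = site_id)
}

subarctic_series <- function(years, seed, trend = 0, gaps = NULL) {
  simulate_temperature(climate_params(years = years, rng_seed = seed,
                                      trend_c_per_decade = trend,
                                      gaps = gaps))
}

laanila_dl_model <- function() {
  model_spec("DL", forcing_params(19.8, 0.73, 6.1, 124.2),
             forcing_start_doy = 89)  # March 30 release
}

# a known DL model inside the calibration bounds plus the noise-free
# observations it generates on a fixed synthetic climate
recovery_fixture <- function(n_years = 9, climate_seed = 11) {
  cl <- subarctic_series(2000:(2001 + n_years), climate_seed)
  truth <- model_spec("DL", forcing_params(22, 0.5, 8, 150),
                      forcing_start_doy = 80)
  yrs <- 2001:(2000 + n_years)
  dates <- as.Date(vapply(yrs, function(y)
    format(predict_budbreak(cl, truth, y)$date), character(1)))
  list(temps = cl, model = truth,
       obs = data.frame(plot_id = "p1", year = yrs, date = dates))
}

write_temp_csv <- function(series, name) {
  path <- file.path(tempdir(), name)
  write_daily_temps(series, path)
  path
}
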