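# Independent brute-force oracles, coded as explicit day-by-day loops with
# scalar arithmetic, deliberately sharing no code with the package.

oracle_forcing_rate <- function(temp, a, b, cc) {
  if (is.na(temp)) return(NA_real_)
  if (temp <= 0) 0 else a / (1 + exp(-b * (temp - cc)))
}

oracle_chilling_rate <- function(temp) {
  if (is.na(temp)) return(NA_real_)
  if (temp <= -3.4 || temp > 10.4) return(0)
  r <- if (temp <= 3.5) 0.159 * temp + 0.506 else -0.159 * temp + 1.621
  max(r, 0)
}

# Day loop over the accumulation window; returns the bud-break Date or NA.
oracle_predict_date <- function(temps, model, year) {
  f <- model$forcing
  end <- as.Date(sprintf("%d-06-30", year))
  if (model$kind == "IA") {
    mm <- as.integer(substr(model$chilling$rest_start, 1, 2))
    d <- as.Date(sprintf("%d-%s", if (mm >= 7) year - 1 else year,
                         model$chilling$rest_start))
    competent <- model$chilling$cu_crit <= 0
    forcing_active <- competent
  } else {
    d <- as.Date(sprintf("%d-01-01", year))
    fstart <- as.Date(model$forcing_start_doy - 1,
                      origin = sprintf("%d-01-01", year))
  }
  cu <- 0
  fu <- 0
  while (d <= end) {
    temp <- temps$temp_c[match(d, temps$date)]
    if (model$kind == "IA") {
      if (forcing_active) {
        fu <- fu + oracle_forcing_rate(temp, f$a, f$b, f$c)
        if (!is.na(fu) && fu >= f$fu_crit) return(d)
      } else {
        cu <- cu + oracle_chilling_rate(temp)
        if (!is.na(cu) && cu >= model$chilling$cu_crit) {
          forcing_active <- TRUE  # forcing starts the following day
        }
      }
    } else {
      if (d >= fstart) {
        fu <- fu + oracle_forcing_rate(temp, f$a, f$b, f$c)
        if (!is.na(fu) && fu >= f$fu_crit) return(d)
      }
    }
    d <- d + 1
  }
  as.Date(NA)
}

# Brute-force daily evaluation of the plot bud-break criteria: explicit
# per-day, per-tree interpolation between the bracketing measurements.
oracle_derive_date <- function(measurements, tree_fraction = 0.5,
                               min_tree_mm = 1, min_plot_fraction = 0.01) {
  trees <- split(measurements, measurements$tree_id)
  trees <- lapply(trees, function(g) g[order(g$date), ])
  lo <- max(as.Date(sapply(trees, function(g) format(min(g$date)))))
  hi <- min(as.Date(sapply(trees, function(g) format(max(g$date)))))
  totals <- sapply(trees, function(g) g$cum_length_mm[nrow(g)])
  interp_one <- function(g, day) {
    i <- findInterval(as.numeric(day), as.numeric(g$date))
    if (g$date[i] == day) return(g$cum_length_mm[i])
    t0 <- as.numeric(g$date[i]); t1 <- as.numeric(g$date[i + 1])
    y0 <- g$cum_length_mm[i]; y1 <- g$cum_length_mm[i + 1]
    y0 + (y1 - y0) * (as.numeric(day) - t0) / (t1 - t0)
  }
  day <- lo
  while (day <= hi) {
    lens <- sapply(trees, interp_one, day = day)
    crit1 <- mean(lens >= min_tree_mm) > tree_fraction
    crit2 <- mean(lens) >= min_plot_fraction * mean(totals)
    if (crit1 && crit2) return(day)
    day <- day + 1
  }
  as.Date(NA)
}
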