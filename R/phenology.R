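#' Temperature responses: forcing and chilling rates
#'
#' `forcing_rate()` is the daily rate of ontogenetic development toward bud
#' break, in forcing units (FU) per day: zero at or below 0 degrees C,
#' otherwise a sigmoid of air temperature,
#' \deqn{m(T) = a / (1 + e^{-b (T - c)}), \quad T > 0.}
#' `chilling_rate()` is the daily rate of rest-breaking in chilling units
#' (CU) per day: a triangular response, zero outside (-3.4, 10.4\] degrees C
#' and peaking near 3.5 degrees C:
#' \deqn{0.159 T + 0.506} on (-3.4, 3.5\] and \deqn{-0.159 T + 1.621} on
#' (3.5, 10.4\]. The published coefficients make the rising branch slightly
#' negative just above -3.4 degrees C (a rounding artifact of the printed
#' constants); chilling cannot be negative, so the rate is clamped at zero.
#'
#' @param temp_c numeric vector of air temperatures (degrees C).
#' @param p a [forcing_params] object.
#' @return numeric vector of rates (FU/day or CU/day).
#' @examples
#' forcing_rate(c(-5, 18.431, 30), forcing_params())
#' chilling_rate(c(-10, 0, 3.5, 15))
#' @export
forcing_rate <- function(temp_c, p = forcing_params()) {
  stopifnot(inherits(p, "forcing_params"))
  r <- p$a / (1 + exp(-p$b * (temp_c - p$c)))
  r[temp_c <= 0] <- 0
  r
}

#' @rdname forcing_rate
#' @export
chilling_rate <- function(temp_c) {
  r <- numeric(length(temp_c))
  up <- temp_c > -3.4 & temp_c <= 3.5
  dn <- temp_c > 3.5 & temp_c <= 10.4
  r[up] <- 0.159 * temp_c[up] + 0.506
  r[dn] <- -0.159 * temp_c[dn] + 1.621
  pmax(r, 0)
}

#' Model parameter objects
#'
#' `forcing_params()` holds the sigmoid parameters and the forcing
#' requirement: `a` the asymptote (FU/day), `b` the slope (1/degC), `c` the
#' inflection temperature (degC), and `fu_crit` the cumulative FU required
#' for bud break. Defaults are the multi-species boreal values commonly
#' used as starting points for calibration. `chilling_params()` holds the
#' chilling requirement `cu_crit` (CU) and the rest-period start date
#' (month-day, conventionally September 1).
#'
#' @param a,b,c,fu_crit sigmoid parameters and forcing requirement.
#' @return a `forcing_params` / `chilling_params` list object.
#' @export
forcing_params <- function(a = 28.361, b = 0.185, c = 18.431, fu_crit = 50) {
  stopifnot(a > 0, b > 0, fu_crit >= 0)
  structure(list(a = a, b = b, c = c, fu_crit = fu_crit),
            class = "forcing_params")
}

#' @rdname forcing_params
#' @param cu_crit chilling requirement (CU).
#' @param rest_start month-day string `"MM-DD"` at which chilling
#'   accumulation begins (in the autumn preceding bud break).
#' @export
chilling_params <- function(cu_crit = 20, rest_start = "09-01") {
  stopifnot(cu_crit >= 0)
  if (is.na(as.Date(paste0("2001-", rest_start)))) {
    stop("`rest_start` must be a valid 'MM-DD' month-day", call. = FALSE)
  }
  structure(list(cu_crit = cu_crit, rest_start = rest_start),
            class = "chilling_params")
}

#' Bud-break model specification
#'
#' Two sequential model structures are supported. Kind `"IA"` accumulates
#' chilling from `rest_start` of the previous autumn; once the chilling
#' requirement `cu_crit` is met (the competence date), forcing accumulates
#' from the following day. Kind `"DL"` is a fixed-date (day-length proxy)
#' model: forcing accumulates from a fixed day of year, inclusive. In both,
#' bud break is predicted on the first day cumulative forcing reaches
#' `fu_crit`.
#'
#' @param kind `"IA"` or `"DL"`.
#' @param forcing a [forcing_params] object.
#' @param chilling a [chilling_params] object (required for `"IA"`).
#' @param forcing_start_doy integer day of year releasing forcing
#'   (required for `"DL"`).
#' @return a `model_spec` object.
#' @examples
#' model_spec("DL", forcing_params(19.8, 0.73, 6.1, 124.2),
#'            forcing_start_doy = 89)
#' @export
model_spec <- function(kind = c("IA", "DL"), forcing = forcing_params(),
                       chilling = NULL, forcing_start_doy = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(forcing, "forcing_params"))
  if (kind == "IA") {
    if (is.null(chilling)) chilling <- chilling_params()
    if (!is.null(forcing_start_doy)) {
      stop("`forcing_start_doy` applies only to kind 'DL'", call. = FALSE)
    }
    stopifnot(inherits(chilling, "chilling_params"))
  } else {
    if (!is.null(chilling)) {
      stop("`chilling` applies only to kind 'IA'", call. = FALSE)
    }
    if (is.null(forcing_start_doy)) forcing_start_doy <- 74L  # March 15
    forcing_start_doy <- as.integer(forcing_start_doy)
    stopifnot(forcing_start_doy >= 1, forcing_start_doy <= 366)
  }
  structure(list(kind = kind, forcing = forcing, chilling = chilling,
                 forcing_start_doy = if (kind == "DL") forcing_start_doy),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  f <- x$forcing
  cat("<model_spec> kind ", x$kind, "\n", sep = "")
  cat(sprintf("  forcing: a=%.4g b=%.4g c=%.4g fu_crit=%.4g\n",
              f$a, f$b, f$c, f$fu_crit))
  if (x$kind == "IA") {
    cat(sprintf("  chilling: cu_crit=%.4g rest_start=%s\n",
                x$chilling$cu_crit, x$chilling$rest_start))
  } else {
    cat("  forcing starts on day of year", x$forcing_start_doy, "\n")
  }
  invisible(x)
}

#' @rdname model_spec
#' @param path JSON file path.
#' @export
write_model_spec <- function(x, path) {
  stopifnot(inherits(x, "model_spec"))
  f <- x$forcing
  obj <- list(kind = x$kind, a = f$a, b = f$b, c = f$c, fu_crit = f$fu_crit)
  if (x$kind == "IA") {
    obj$cu_crit <- x$chilling$cu_crit
    obj$rest_start <- x$chilling$rest_start
  } else {
    obj$forcing_start_doy <- x$forcing_start_doy
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_spec
#' @export
read_model_spec <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  fp <- forcing_params(o$a, o$b, o$c, o$fu_crit)
  if (identical(o$kind, "IA")) {
    model_spec("IA", fp, chilling = chilling_params(o$cu_crit, o$rest_start))
  } else {
    model_spec("DL", fp, forcing_start_doy = o$forcing_start_doy)
  }
}

# Accumulation window for one bud-break year. IA spans the most recent
# rest_start before the bud-break spring (an autumn month-day falls in the
# previous calendar year) through June 30; DL spans January 1 to June 30.
budbreak_window <- function(model, year) {
  end <- as.Date(sprintf("%d-06-30", year))
  start <- if (model$kind == "IA") {
    rest_start_date(model$chilling$rest_start, year)
  } else {
    as.Date(sprintf("%d-01-01", year))
  }
  c(start, end)
}

rest_start_date <- function(rest_start, year) {
  mm <- as.integer(substr(rest_start, 1, 2))
  as.Date(sprintf("%d-%s", if (mm >= 7) year - 1L else year, rest_start))
}

#' Predict the bud-break date for one year
#'
#' Runs the accumulation scheme of `model` over the daily temperatures and
#' returns the first day on which cumulative forcing reaches `fu_crit`, or
#' no date if the requirement is not met by June 30. Chilling (kind
#' `"IA"`) accumulates from `rest_start` of the previous year; forcing
#' starts the day after the chilling requirement is met (no same-day
#' double counting). For kind `"DL"` forcing starts on
#' `forcing_start_doy`, that day inclusive. Accumulation is at whole-day
#' granularity with no sub-daily interpolation. A gap on any day the model
#' actually consumes is an error naming the missing date.
#'
#' @param temps a [daily_temps] object covering the model's window for
#'   `year` (IA: `rest_start` of `year - 1` through June 30 of `year`;
#'   DL: January 1 through June 30 of `year`).
#' @param model a [model_spec].
#' @param year integer bud-break year.
#' @return A `budbreak_prediction`: list with `year`, `date` (`Date` or
#'   `NA`), `doy`, `forcing_attained` (cumulative FU at the end of the
#'   window), and `competence_date` (`Date` or `NA`).
#' @export
predict_budbreak <- function(temps, model, year) {
  stopifnot(inherits(temps, "daily_temps"), inherits(model, "model_spec"))
  year <- as.integer(year)
  win <- budbreak_window(model, year)
  if (nrow(temps) == 0 || temps$date[1] > win[1] ||
      temps$date[nrow(temps)] < win[2]) {
    stop("temperature series does not cover the window ", format(win[1]),
         " to ", format(win[2]), call. = FALSE)
  }
  idx <- which(temps$date >= win[1] & temps$date <= win[2])
  dates <- temps$date[idx]
  tv <- temps$temp_c[idx]

  if (model$kind == "IA") {
    consume_from <- 1L
    cu <- cumsum(ifelse(is.na(tv), NA_real_, chilling_rate(tv)))
    comp_i <- match(TRUE, !is.na(cu) & cu >= model$chilling$cu_crit)
    if (model$chilling$cu_crit == 0) comp_i <- 0L  # competent at window start
    frc_from <- if (is.na(comp_i)) NA_integer_ else comp_i + 1L
    competence_date <- if (is.na(comp_i) || comp_i == 0L) {
      if (identical(comp_i, 0L)) dates[1] - 1 else as.Date(NA)
    } else dates[comp_i]
  } else {
    start_date <- as.Date(model$forcing_start_doy - 1L,
                          origin = sprintf("%d-01-01", year))
    frc_from <- match(start_date, dates)
    consume_from <- frc_from
    competence_date <- start_date
  }

  fu_cum_end <- 0
  bb_i <- NA_integer_
  first_na <- match(TRUE, is.na(tv))
  if (!is.na(frc_from) && frc_from <= length(tv)) {
    fr <- forcing_rate(tv[frc_from:length(tv)], model$forcing)
    fu <- cumsum(fr)  # NA propagates past any gap
    bb_rel <- match(TRUE, !is.na(fu) & fu >= model$forcing$fu_crit)
    bb_i <- if (is.na(bb_rel)) NA_integer_ else frc_from + bb_rel - 1L
    last_ok <- length(fu)
    if (anyNA(fu)) last_ok <- match(TRUE, is.na(fu)) - 1L
    fu_cum_end <- if (last_ok >= 1) fu[last_ok] else 0
  }

  # a gap is fatal only if the model consumed it: before the break date,
  # or anywhere in the consumed window when the requirement is not met
  if (!is.na(first_na) && !is.na(consume_from) && first_na >= consume_from &&
      (is.na(bb_i) || first_na <= bb_i)) {
    stop("temperature gap on ", format(dates[first_na]),
         " inside the consumed accumulation window", call. = FALSE)
  }

  date <- if (is.na(bb_i)) as.Date(NA) else dates[bb_i]
  structure(list(
    year = year,
    date = date,
    doy = if (is.na(bb_i)) NA_integer_ else as.integer(strftime(date, "%j")),
    forcing_attained = fu_cum_end,
    competence_date = competence_date
  ), class = "budbreak_prediction")
}

#' @export
print.budbreak_prediction <- function(x, ...) {
  cat("<budbreak_prediction> year ", x$year, ": ", sep = "")
  if (is.na(x$date)) {
    cat("forcing requirement not reached (", round(x$forcing_attained, 2),
        " FU attained)\n", sep = "")
  } else {
    cat(format(x$date), " (doy ", x$doy, ")\n", sep = "")
  }
  invisible(x)
}

#' Chilling and forcing accumulation curves
#'
#' Daily cumulative chilling and forcing totals over the model's window for
#' one year, for diagnostics and plotting. Both columns are non-decreasing
#' and the final forcing total equals `forcing_attained` from
#' [predict_budbreak()].
#'
#' @inheritParams predict_budbreak
#' @return data.frame with columns `date`, `cu_cum`, `fu_cum`.
#' @export
accumulation_curves <- function(temps, model, year) {
  pred <- predict_budbreak(temps, model, year)  # validates window and gaps
  win <- budbreak_window(model, as.integer(year))
  idx <- which(temps$date >= win[1] & temps$date <= win[2])
  dates <- temps$date[idx]
  tv <- temps$temp_c[idx]
  first_na <- match(TRUE, is.na(tv))
  if (!is.na(first_na)) {  # gap after bud break: truncate the curves there
    dates <- dates[seq_len(first_na - 1L)]
    tv <- tv[seq_len(first_na - 1L)]
  }
  n <- length(tv)
  cu <- numeric(n)
  fu <- numeric(n)
  if (model$kind == "IA") {
    cr <- chilling_rate(tv)
    cu_raw <- cumsum(cr)
    comp_i <- if (model$chilling$cu_crit == 0) 0L else
      match(TRUE, cu_raw >= model$chilling$cu_crit)
    if (is.na(comp_i)) {
      cu <- cu_raw
      frc_from <- NA_integer_
    } else {
      # chilling stops contributing once competence is reached
      cap <- if (comp_i == 0L) 0 else cu_raw[comp_i]
      cu <- pmin(cu_raw, cap)
      frc_from <- comp_i + 1L
    }
  } else {
    frc_from <- match(as.Date(model$forcing_start_doy - 1L,
                              origin = sprintf("%d-01-01", year)), dates)
  }
  if (!is.na(frc_from) && frc_from <= n) {
    fu[frc_from:n] <- cumsum(forcing_rate(tv[frc_from:n], model$forcing))
  }
  out <- data.frame(date = dates, cu_cum = cu, fu_cum = fu)
  attr(out, "prediction") <- pred
  out
}
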