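#' Reconstruct a bud-break series from a station temperature record
#'
#' Applies an offset-adjusted daily temperature record to a calibrated
#' bud-break model year by year. A year is omitted (with reason
#' `"omitted_missing_temps"`) when any daily value inside the omission
#' window (April 1 to May 31 by default) is a gap, or when a gap falls
#' inside the window the model actually consumes (for kind `"IA"` this
#' includes the previous autumn/winter chilling window, which is stricter
#' than an April-May rule alone). Years where the forcing requirement is
#' not met by June 30 are marked `"not_reached"`.
#'
#' @param station [daily_temps] spanning the requested years (gaps
#'   allowed; they only cost the affected years).
#' @param adj an `offset_adjustment` (or a number of degrees C) applied to
#'   the whole record before prediction; `NULL` for none.
#' @param model a [model_spec].
#' @param years integer vector of bud-break years.
#' @param omit_window character `c("MM-DD", "MM-DD")` gap-screening window
#'   within each bud-break year.
#' @return A `reconstruction` object: data.frame with columns `year`,
#'   `doy`, `status` (`"predicted"`, `"omitted_missing_temps"`,
#'   `"not_reached"`), with the model and site id as attributes.
#' @export
reconstruct_budbreak <- function(station, adj = NULL, model, years,
                                 omit_window = c("04-01", "05-31")) {
  stopifnot(inherits(station, "daily_temps"), inherits(model, "model_spec"))
  years <- as.integer(years)
  if (length(years) == 0) stop("empty year range", call. = FALSE)
  temps <- if (is.null(adj)) station else adjust_temps(station, adj)
  rows <- lapply(years, function(y) {
    w0 <- as.Date(sprintf("%d-%s", y, omit_window[1]))
    w1 <- as.Date(sprintf("%d-%s", y, omit_window[2]))
    gap_in_win <- any(is.na(temps$temp_c[temps$date >= w0 & temps$date <= w1]))
    if (gap_in_win) {
      return(data.frame(year = y, doy = NA_integer_,
                        status = "omitted_missing_temps"))
    }
    p <- tryCatch(predict_budbreak(temps, model, y), error = function(e) e)
    if (inherits(p, "error")) {
      status <- if (grepl("gap", conditionMessage(p)))
        "omitted_missing_temps" else stop(p)
      return(data.frame(year = y, doy = NA_integer_, status = status))
    }
    if (is.na(p$date)) {
      data.frame(year = y, doy = NA_integer_, status = "not_reached")
    } else {
      data.frame(year = y, doy = p$doy, status = "predicted")
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "model") <- model
  attr(out, "site_id") <- attr(station, "site_id")
  class(out) <- c("reconstruction", "data.frame")
  out
}

#' @export
print.reconstruction <- function(x, ...) {
  cat("<reconstruction> site ", attr(x, "site_id"), ", ", nrow(x),
      " year(s): ", sum(x$status == "predicted"), " predicted, ",
      sum(x$status == "omitted_missing_temps"), " omitted, ",
      sum(x$status == "not_reached"), " not reached\n", sep = "")
  invisible(x)
}

#' @rdname reconstruct_budbreak
#' @param x a `reconstruction` object.
#' @export
omitted_years <- function(x) {
  stopifnot(inherits(x, "reconstruction"))
  x$year[x$status == "omitted_missing_temps"]
}

#' @rdname reconstruct_budbreak
#' @param path CSV path; columns `year,doy,status`.
#' @export
write_reconstruction_csv <- function(x, path) {
  stopifnot(inherits(x, "reconstruction"))
  utils::write.csv(as.data.frame(x)[c("year", "doy", "status")], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Lag-1 residual autocorrelation test
#'
#' Durbin-Watson style statistic `sum(diff(e)^2) / sum(e^2)` (near 2 under
#' independence, toward 0 under positive and toward 4 under negative
#' lag-1 autocorrelation) with a two-sided permutation p-value: residuals
#' are randomly permuted and the departure `|DW - 2|` compared against the
#' permutation distribution.
#'
#' @param residuals numeric vector, at least 10 values, not constant.
#' @param n_perm number of permutations.
#' @return list with `statistic` (DW) and `p_value`.
#' @export
autocorrelation_test <- function(residuals, n_perm = 999) {
  residuals <- residuals[!is.na(residuals)]
  if (length(residuals) < 10) stop("need at least 10 residuals", call. = FALSE)
  if (stats::sd(residuals) == 0) stop("constant residuals", call. = FALSE)
  dw <- function(e) sum(diff(e)^2) / sum(e^2)
  obs <- dw(residuals)
  perm <- vapply(seq_len(n_perm),
                 function(i) dw(sample(residuals)), numeric(1))
  p <- (1 + sum(abs(perm - 2) >= abs(obs - 2))) / (n_perm + 1)
  list(statistic = obs, p_value = p)
}

#' Linear trend under autoregressive errors
#'
#' Fits `doy = b0 + b1 * year + e` with AR(`ar_order`) errors by two
#' estimation paths: maximum likelihood of the joint AR-error regression
#' (generalized least squares via [nlme::gls()] with an AR correlation
#' structure indexed by calendar year, so omitted years enter as genuine
#' gaps) and ordinary least squares of the plain regression. Both
#' inference sets are reported, as are a lag-1 residual autocorrelation
#' test and the change in bud-break timing implied by the ML slope over a
#' stated horizon (`slope * horizon_years`, in days).
#'
#' @param series a `reconstruction` object or a data.frame with `year` and
#'   `doy` (`NA` for omitted years).
#' @param ar_order integer AR order, or `"auto"` to pick order 0-2 by AIC.
#' @param horizon_years horizon for the implied change, in years.
#' @param n_perm permutations for the residual autocorrelation test.
#' @return A `trend_result`: list with `slope_ml`, `se_ml`, `p_ml`,
#'   `slope_ols`, `se_ols`, `p_ols`, `intercept_ml`, `intercept_ols`,
#'   `ar_order`, `ar_coef`, `dw_statistic`, `dw_p_value`,
#'   `implied_change_days`, `horizon_years`, `n_years`.
#' @export
fit_trend <- function(series, ar_order = "auto", horizon_years = 100,
                      n_perm = 999) {
  df <- as.data.frame(series)
  stopifnot(all(c("year", "doy") %in% names(df)))
  df <- df[order(df$year), ]
  ok <- !is.na(df$doy)
  if (sum(ok) < 20) stop("need at least 20 usable years", call. = FALSE)

  fit_ols <- stats::lm(doy ~ year, data = df[ok, ])
  sm <- summary(fit_ols)$coefficients
  slope_ols <- sm["year", "Estimate"]
  se_ols <- sm["year", "Std. Error"]
  p_ols <- sm["year", "Pr(>|t|)"]
  res_ols <- stats::residuals(fit_ols)

  dat <- df[ok, c("year", "doy")]
  if (stats::sd(res_ols) < 1e-8) {
    # an exact line: AR structure is unidentifiable and irrelevant
    slope_ml <- slope_ols; se_ml <- se_ols; p_ml <- p_ols
    intercept_ml <- stats::coef(fit_ols)[1]
    order_used <- 0L
    ar_coef <- numeric(0)
  } else {
    # AR correlation indexed by calendar year, so omitted years are gaps
    fit_ml_order <- function(p) {
      corr <- if (p == 0) NULL
        else if (p == 1) nlme::corAR1(form = ~year)
        else nlme::corARMA(p = p, form = ~year)
      nlme::gls(doy ~ year, data = dat, correlation = corr, method = "ML")
    }
    if (identical(ar_order, "auto")) {
      fits <- lapply(0:2, function(p) tryCatch(fit_ml_order(p),
                                               error = function(e) NULL))
      aics <- vapply(fits, function(f) if (is.null(f)) Inf else stats::AIC(f),
                     numeric(1))
      if (all(is.infinite(aics))) {
        stop("AR fit failed at every candidate order", call. = FALSE)
      }
      order_used <- which.min(aics) - 1L
      fit_ml <- fits[[order_used + 1L]]
    } else {
      order_used <- as.integer(ar_order)
      fit_ml <- tryCatch(fit_ml_order(order_used), error = function(e)
        stop("AR(", order_used, ") ML fit failed: ", conditionMessage(e),
             call. = FALSE))
    }
    tt <- summary(fit_ml)$tTable
    slope_ml <- tt["year", "Value"]
    se_ml <- tt["year", "Std.Error"]
    p_ml <- tt["year", "p-value"]
    intercept_ml <- tt["(Intercept)", "Value"]
    ar_coef <- if (order_used > 0) {
      unname(stats::coef(fit_ml$modelStruct$corStruct,
                         unconstrained = FALSE))
    } else numeric(0)
  }

  act <- autocorrelation_test(res_ols, n_perm = n_perm)
  structure(list(
    slope_ml = slope_ml, se_ml = se_ml, p_ml = unname(p_ml),
    slope_ols = unname(slope_ols), se_ols = unname(se_ols),
    p_ols = unname(p_ols),
    intercept_ml = unname(intercept_ml),
    intercept_ols = unname(stats::coef(fit_ols)[1]),
    ar_order = order_used, ar_coef = unname(ar_coef),
    dw_statistic = act$statistic, dw_p_value = act$p_value,
    implied_change_days = implied_change(slope_ml, horizon_years),
    horizon_years = horizon_years, n_years = sum(ok)),
    class = "trend_result")
}

#' @rdname fit_trend
#' @param slope trend slope in days per year.
#' @return `implied_change()` returns `slope * horizon_years`, days.
#' @export
implied_change <- function(slope, horizon_years) {
  slope * horizon_years
}

#' @export
print.trend_result <- function(x, ...) {
  cat("<trend_result> n =", x$n_years, "years, AR order", x$ar_order, "\n")
  cat(sprintf("  ML : slope %+.4f d/yr (se %.4f, p %.4f)\n",
              x$slope_ml, x$se_ml, x$p_ml))
  cat(sprintf("  OLS: slope %+.4f d/yr (se %.4f, p %.4f)\n",
              x$slope_ols, x$se_ols, x$p_ols))
  cat(sprintf("  lag-1 autocorrelation: DW %.3f (perm p %.4f)\n",
              x$dw_statistic, x$dw_p_value))
  cat(sprintf("  implied change over %d years: %+.2f days\n",
              x$horizon_years, x$implied_change_days))
  invisible(x)
}

#' @rdname fit_trend
#' @param x a `trend_result`.
#' @param path JSON file path.
#' @export
write_trend <- function(x, path) {
  stopifnot(inherits(x, "trend_result"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
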