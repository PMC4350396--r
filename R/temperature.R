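#' Daily temperature series
#'
#' Construct a validated daily mean air-temperature series for one site.
#' The series is stored over a contiguous calendar span: every date between
#' the first and last supplied date is present, and dates with no
#' measurement carry `NA` (an explicit gap, never interpolated).
#'
#' @param date `Date` vector (or ISO-8601 strings). Duplicates are an error;
#'   unordered input is sorted with a warning.
#' @param temp_c numeric vector of mean daily temperatures (degrees C).
#'   `NA` marks a gap. Non-missing values must lie in the sanity window
#'   \[-60, +45\] degrees C.
#' @param site_id character label for the site.
#' @return A `daily_temps` object: a `data.frame` with columns `date` and
#'   `temp_c` over a contiguous span, with attribute `site_id`.
#' @examples
#' s <- daily_temps(as.Date("2001-01-01") + 0:2, c(-5, NA, -3.2))
#' temperature_gaps(s)
#' @export
daily_temps <- function(date, temp_c, site_id = "site") {
  date <- as.Date(date)
  temp_c <- as.numeric(temp_c)
  if (length(date) != length(temp_c)) {
    stop("`date` and `temp_c` must have the same length", call. = FALSE)
  }
  if (anyNA(date)) stop("unparseable date in input", call. = FALSE)
  if (anyDuplicated(date)) {
    stop("duplicate date(s): ",
         paste(format(unique(date[duplicated(date)])), collapse = ", "),
         call. = FALSE)
  }
  if (is.unsorted(date)) {
    warning("dates out of order; sorting", call. = FALSE)
    o <- order(date)
    date <- date[o]
    temp_c <- temp_c[o]
  }
  bad <- !is.na(temp_c) & (temp_c < -60 | temp_c > 45)
  if (any(bad)) {
    stop("temperature outside sanity window [-60, 45] on ",
         paste(format(date[bad]), collapse = ", "), call. = FALSE)
  }
  if (length(date) > 0) {
    full <- seq(date[1], date[length(date)], by = "day")
    tmp <- rep(NA_real_, length(full))
    tmp[match(date, full)] <- temp_c
    date <- full
    temp_c <- tmp
  }
  out <- data.frame(date = date, temp_c = temp_c)
  attr(out, "site_id") <- site_id
  class(out) <- c("daily_temps", "data.frame")
  out
}

#' @export
print.daily_temps <- function(x, ...) {
  n <- nrow(x)
  cat("<daily_temps> site ", attr(x, "site_id"), ": ", n, " days", sep = "")
  if (n > 0) {
    cat(" (", format(x$date[1]), " to ", format(x$date[n]), "), ",
        sum(is.na(x$temp_c)), " gap(s)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @rdname daily_temps
#' @param x a `daily_temps` object.
#' @export
temperature_gaps <- function(x) {
  stopifnot(inherits(x, "daily_temps"))
  x$date[is.na(x$temp_c)]
}

#' @rdname daily_temps
#' @export
site_id <- function(x) attr(x, "site_id")

#' Read and write daily temperature CSV files
#'
#' The file format is fixed for reproducibility: comma-separated, UTF-8,
#' header `date,temp_c`, ISO-8601 dates, `.` decimal mark. A blank
#' temperature cell denotes a gap. Writing uses a canonical number format
#' so that write-read-write is byte-stable.
#'
#' @param path file path.
#' @param site_id site label attached to the returned series.
#' @return `read_daily_temps()` returns a [daily_temps] object.
#' @export
read_daily_temps <- function(path, site_id = basename(path)) {
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!identical(names(raw), c("date", "temp_c"))) {
    stop("expected header 'date,temp_c' in ", path, call. = FALSE)
  }
  if (nrow(raw) == 0) {
    return(daily_temps(as.Date(character()), numeric(), site_id = site_id))
  }
  d <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(d)) {
    stop("malformed date at line ", which(is.na(d))[1] + 1L, " of ", path,
         call. = FALSE)
  }
  blank <- raw$temp_c == ""
  v <- suppressWarnings(as.numeric(raw$temp_c))
  bad <- !blank & is.na(v)
  if (any(bad)) {
    stop("non-numeric temperature at line ", which(bad)[1] + 1L, " of ", path,
         call. = FALSE)
  }
  v[blank] <- NA_real_
  daily_temps(d, v, site_id = site_id)
}

#' @rdname read_daily_temps
#' @param x a [daily_temps] object.
#' @export
write_daily_temps <- function(x, path) {
  stopifnot(inherits(x, "daily_temps"))
  val <- ifelse(is.na(x$temp_c), "",
                formatC(x$temp_c, digits = 15, format = "g"))
  lines <- c("date,temp_c", paste(format(x$date), val, sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Hourly temperature series and daily aggregation
#'
#' On-site loggers record air temperature (sub-)hourly; models are driven
#' by mean daily values. `aggregate_hourly_to_daily()` averages all
#' observations within each calendar day; days with fewer than `min_hours`
#' observations become gaps rather than biased means.
#'
#' @param timestamp `POSIXct` vector (or ISO-8601 strings with hour).
#' @param temp_c numeric temperatures (degrees C), sanity window
#'   \[-60, 45\].
#' @param site_id site label.
#' @return `hourly_temps()` returns an `hourly_temps` data.frame;
#'   `aggregate_hourly_to_daily()` a [daily_temps] object.
#' @export
hourly_temps <- function(timestamp, temp_c, site_id = "site") {
  timestamp <- as.POSIXct(timestamp, tz = "UTC")
  temp_c <- as.numeric(temp_c)
  if (anyNA(timestamp)) stop("unparseable timestamp", call. = FALSE)
  if (is.unsorted(as.numeric(timestamp), strictly = TRUE)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(temp_c < -60 | temp_c > 45, na.rm = TRUE)) {
    stop("temperature outside sanity window [-60, 45]", call. = FALSE)
  }
  out <- data.frame(timestamp = timestamp, temp_c = temp_c)
  attr(out, "site_id") <- site_id
  class(out) <- c("hourly_temps", "data.frame")
  out
}

#' @rdname hourly_temps
#' @param path file path with header `timestamp,temp_c`.
#' @export
read_hourly_temps <- function(path, site_id = basename(path)) {
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!identical(names(raw), c("timestamp", "temp_c"))) {
    stop("expected header 'timestamp,temp_c' in ", path, call. = FALSE)
  }
  ts <- as.POSIXct(raw$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  if (anyNA(ts)) {
    stop("malformed timestamp at line ", which(is.na(ts))[1] + 1L, " of ",
         path, call. = FALSE)
  }
  hourly_temps(ts, as.numeric(raw$temp_c), site_id = site_id)
}

#' @rdname hourly_temps
#' @param h an `hourly_temps` object.
#' @param min_hours minimum number of observations a calendar day needs to
#'   receive a mean; default 20 tolerates occasional dropped logger
#'   readings while rejecting badly truncated days.
#' @export
aggregate_hourly_to_daily <- function(h, min_hours = 20) {
  stopifnot(inherits(h, "hourly_temps"))
  if (min_hours < 1 || min_hours > 24) {
    stop("`min_hours` must be in [1, 24]", call. = FALSE)
  }
  day <- as.Date(h$timestamp, tz = "UTC")
  means <- tapply(h$temp_c, day, mean)
  counts <- tapply(h$temp_c, day, length)
  means[counts < min_hours] <- NA_real_
  daily_temps(as.Date(names(means)), as.numeric(means),
              site_id = attr(h, "site_id"))
}

#' Offset adjustment between a site and a reference station
#'
#' A short on-site record is tied to a long station record through an
#' additive offset: the mean site-minus-station difference over a window of
#' calendar months and years (April-May of the calibration years for the
#' reconstruction use case; arbitrary month sets for logger calibration).
#' Sign convention: `station + offset` approximates the site.
#'
#' @param site,station [daily_temps] objects with overlapping span.
#' @param months integer months (1-12) defining the window.
#' @param years integer years defining the window.
#' @return An `offset_adjustment` object: list with `offset_c`, `months`,
#'   `years`.
#' @export
compute_offset <- function(site, station, months = c(4L, 5L), years) {
  stopifnot(inherits(site, "daily_temps"), inherits(station, "daily_temps"))
  months <- as.integer(months)
  years <- as.integer(years)
  pick <- function(s) {
    m <- as.integer(format(s$date, "%m"))
    y <- as.integer(format(s$date, "%Y"))
    s[m %in% months & y %in% years, , drop = FALSE]
  }
  a <- pick(site)
  b <- pick(station)
  common <- merge(a, b, by = "date", suffixes = c(".site", ".station"))
  common <- common[!is.na(common$temp_c.site) & !is.na(common$temp_c.station), ]
  # every (month, year) cell of the window must contribute
  want <- expand.grid(month = months, year = years)
  have <- unique(data.frame(
    month = as.integer(format(common$date, "%m")),
    year = as.integer(format(common$date, "%Y"))))
  miss <- want[!paste(want$month, want$year) %in% paste(have$month, have$year), ]
  if (nrow(miss) > 0) {
    stop("no overlapping non-gap values for window cell(s): ",
         paste(sprintf("%d-%02d", miss$year, miss$month), collapse = ", "),
         call. = FALSE)
  }
  out <- list(offset_c = mean(common$temp_c.site - common$temp_c.station),
              months = months, years = years)
  class(out) <- "offset_adjustment"
  out
}

#' @rdname compute_offset
#' @param offset_c additive constant (degrees C).
#' @export
offset_adjustment <- function(offset_c, months = integer(), years = integer()) {
  stopifnot(is.finite(offset_c))
  out <- list(offset_c = as.numeric(offset_c), months = as.integer(months),
              years = as.integer(years))
  class(out) <- "offset_adjustment"
  out
}

#' @export
print.offset_adjustment <- function(x, ...) {
  cat(sprintf("<offset_adjustment> %+.3f degC (months %s; %d year(s))\n",
              x$offset_c, paste(x$months, collapse = ","), length(x$years)))
  invisible(x)
}

#' @rdname compute_offset
#' @param series a [daily_temps] object.
#' @param adj an `offset_adjustment` (or a bare number of degrees C).
#' @return `adjust_temps()` returns the shifted series; gaps are unchanged.
#' @export
adjust_temps <- function(series, adj) {
  stopifnot(inherits(series, "daily_temps"))
  off <- if (inherits(adj, "offset_adjustment")) adj$offset_c else as.numeric(adj)
  series$temp_c <- series$temp_c + off
  series
}

#' @rdname compute_offset
#' @param path JSON file path.
#' @export
write_offset <- function(adj, path) {
  stopifnot(inherits(adj, "offset_adjustment"))
  jsonlite::write_json(list(offset_c = adj$offset_c, months = adj$months,
                            years = adj$years),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname compute_offset
#' @export
read_offset <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  offset_adjustment(x$offset_c, x$months, x$years)
}
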