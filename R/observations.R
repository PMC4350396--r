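#' Read per-tree growth measurements
#'
#' Cumulative leader-shoot length since season start, measured repeatedly
#' (usually weekly) on each sample tree of a plot. Per tree the cumulative
#' length must be non-negative and non-decreasing over time.
#'
#' @param path CSV with header `plot_id,tree_id,date,cum_length_mm`.
#' @return data.frame with those columns, `date` parsed as `Date`.
#' @export
read_growth_csv <- function(path) {
  x <- utils::read.csv(path, colClasses = c("character", "character",
                                            "character", "numeric"))
  if (!identical(names(x), c("plot_id", "tree_id", "date", "cum_length_mm"))) {
    stop("expected header 'plot_id,tree_id,date,cum_length_mm' in ", path,
         call. = FALSE)
  }
  x$date <- as.Date(x$date)
  if (anyNA(x$date)) stop("malformed date in ", path, call. = FALSE)
  validate_growth(x)
  x
}

# cumulative length restarts at zero each season, so monotonicity is a
# per-tree, per-season constraint
validate_growth <- function(x) {
  if (any(x$cum_length_mm < 0)) {
    stop("negative cumulative length", call. = FALSE)
  }
  season <- format(x$date, "%Y")
  for (key in unique(paste(x$tree_id, season))) {
    g <- x[paste(x$tree_id, season) == key, ]
    g <- g[order(g$date), ]
    if (is.unsorted(g$cum_length_mm)) {
      stop("non-monotone cumulative length for tree ", g$tree_id[1],
           call. = FALSE)
    }
  }
  invisible(x)
}

#' Bud-break detection rule
#'
#' A plot's bud break is declared on the earliest day on which (1) the
#' fraction of sample trees with at least `min_tree_mm` of elongation
#' strictly exceeds `tree_fraction`, and (2) the plot-mean increment is at
#' least `min_plot_fraction` of the plot-mean season total. Defaults
#' encode the "more than half of trees at least 1 mm, plot mean at least
#' 1 % of season growth" convention. "More than half" is strict: 5 of 10
#' trees does not qualify.
#'
#' @param tree_fraction fraction of trees that must exceed the per-tree
#'   threshold (strict inequality).
#' @param min_tree_mm per-tree elongation threshold (mm).
#' @param min_plot_fraction plot-mean increment threshold as a fraction of
#'   plot-mean season total.
#' @export
budbreak_rule <- function(tree_fraction = 0.5, min_tree_mm = 1,
                          min_plot_fraction = 0.01) {
  stopifnot(tree_fraction > 0, tree_fraction <= 1,
            min_tree_mm > 0, min_plot_fraction > 0)
  structure(list(tree_fraction = tree_fraction, min_tree_mm = min_tree_mm,
                 min_plot_fraction = min_plot_fraction),
            class = "budbreak_rule")
}

#' Derive the observed bud-break date of one plot-year
#'
#' Each tree's cumulative-length series is linearly interpolated to daily
#' resolution between consecutive measurement dates (per-tree first, so
#' the criteria can be met between weekly visits); the rule of
#' [budbreak_rule()] is then evaluated day by day. The season total of a
#' tree is its final cumulative measurement; the plot total is the mean of
#' tree totals. The result is at whole-day resolution.
#'
#' @param measurements data.frame with columns `plot_id`, `tree_id`,
#'   `date`, `cum_length_mm` for a single plot and season (at least two
#'   measurement dates per tree).
#' @param rule a [budbreak_rule].
#' @return A `budbreak_observation`: list with `plot_id`, `year`, `date`,
#'   `doy` and `status` (`"detected"`, `"left_censored"` when the criteria
#'   already hold at the first evaluable day, or `"not_detected"` with
#'   `date = NA` when they never hold).
#' @export
derive_budbreak_date <- function(measurements, rule = budbreak_rule()) {
  stopifnot(is.data.frame(measurements))
  m <- measurements
  m$date <- as.Date(m$date)
  plot_id <- unique(m$plot_id)
  if (length(plot_id) != 1) stop("measurements must be one plot", call. = FALSE)
  year <- unique(as.integer(format(m$date, "%Y")))
  if (length(year) != 1) stop("measurements must be one season", call. = FALSE)
  validate_growth(m)
  trees <- unique(m$tree_id)
  per_tree <- lapply(trees, function(id) {
    g <- m[m$tree_id == id, ]
    g <- g[order(g$date), ]
    if (nrow(g) < 2) stop("tree ", id, " has fewer than 2 measurements",
                          call. = FALSE)
    g
  })
  # evaluate where every tree's interpolation is defined
  lo <- as.Date(max(vapply(per_tree, function(g) as.numeric(min(g$date)),
                           numeric(1))), origin = "1970-01-01")
  hi <- as.Date(min(vapply(per_tree, function(g) as.numeric(max(g$date)),
                           numeric(1))), origin = "1970-01-01")
  if (lo > hi) stop("tree measurement ranges do not overlap", call. = FALSE)
  grid <- seq(lo, hi, by = "day")
  len <- vapply(per_tree, function(g) {
    stats::approx(as.numeric(g$date), g$cum_length_mm, xout = as.numeric(grid),
                  method = "linear")$y
  }, numeric(length(grid)))
  len <- matrix(len, nrow = length(grid))
  totals <- vapply(per_tree, function(g) g$cum_length_mm[nrow(g)], numeric(1))
  frac_ok <- rowMeans(len >= rule$min_tree_mm) > rule$tree_fraction
  mean_ok <- rowMeans(len) >= rule$min_plot_fraction * mean(totals)
  hit <- match(TRUE, frac_ok & mean_ok)
  if (is.na(hit)) {
    res <- list(plot_id = plot_id, year = year, date = as.Date(NA),
                doy = NA_integer_, status = "not_detected")
  } else {
    d <- grid[hit]
    res <- list(plot_id = plot_id, year = year, date = d,
                doy = as.integer(strftime(d, "%j")),
                status = if (hit == 1L) "left_censored" else "detected")
  }
  class(res) <- "budbreak_observation"
  res
}

#' @export
print.budbreak_observation <- function(x, ...) {
  cat("<budbreak_observation> plot ", x$plot_id, ", year ", x$year, ": ",
      sep = "")
  if (x$status == "not_detected") cat("no bud break detected\n")
  else cat(format(x$date), " (doy ", x$doy, ", ", x$status, ")\n", sep = "")
  invisible(x)
}

#' Bud-break observations as a table
#'
#' `as_observation_table()` binds `budbreak_observation` objects (or a
#' data.frame already holding `plot_id,year,date`) into the canonical
#' observation table with a `doy` column. `read_observations_csv()` /
#' `write_observations_csv()` use the same schema on disk.
#'
#' @param x list of `budbreak_observation` objects or a data.frame.
#' @return data.frame with columns `plot_id`, `year`, `date`, `doy`.
#' @export
as_observation_table <- function(x) {
  if (is.data.frame(x)) {
    out <- x
    out$date <- as.Date(out$date)
    out$year <- as.integer(if ("year" %in% names(out)) out$year
                           else format(out$date, "%Y"))
  } else {
    x <- Filter(function(o) !is.na(o$date), x)
    out <- data.frame(
      plot_id = vapply(x, `[[`, character(1), "plot_id"),
      year = vapply(x, `[[`, integer(1), "year"),
      date = as.Date(vapply(x, function(o) format(o$date), character(1))))
  }
  out$doy <- as.integer(strftime(out$date, "%j"))
  if (anyDuplicated(out[c("plot_id", "year")])) {
    stop("more than one observation for some plot-year", call. = FALSE)
  }
  out[order(out$plot_id, out$year), , drop = FALSE]
}

#' @rdname as_observation_table
#' @param path CSV path, header `plot_id,year,date,doy`.
#' @export
read_observations_csv <- function(path) {
  x <- utils::read.csv(path, colClasses = c(plot_id = "character"))
  x$date <- as.Date(x$date)
  as_observation_table(x)
}

#' @rdname as_observation_table
#' @export
write_observations_csv <- function(x, path) {
  utils::write.csv(as_observation_table(x)[c("plot_id", "year", "date", "doy")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Observed bud-break dates from the northern-Finland sapling plots
#'
#' The bud-break dates observed in five Scots pine sapling plots at two
#' high-latitude sites (Laanila, Inari and Vanttauskoski, Rovaniemi),
#' three seasons per plot, shipped as a plain-text fixture. A `site`
#' column distinguishes the two stands.
#'
#' @return data.frame with columns `site`, `plot_id`, `year`, `date`,
#'   `doy`.
#' @export
observed_budbreak <- function() {
  path <- system.file("extdata", "observed_budbreak.csv",
                      package = "budbreakr", mustWork = TRUE)
  x <- utils::read.csv(path, colClasses = c(site = "character",
                                            plot_id = "character"))
  x$date <- as.Date(x$date)
  x$year <- as.integer(format(x$date, "%Y"))
  x$doy <- as.integer(strftime(x$date, "%j"))
  x
}

# calendar position of a date within the year, leap-year safe: month-day
# mapped onto a fixed non-leap reference year
month_day_position <- function(date) {
  as.integer(strftime(as.Date(paste0("2001-", format(date, "%m-%d"))), "%j"))
}

#' Summary statistics of bud-break observations
#'
#' Per-plot range of bud-break dates (max minus min of the month-day
#' calendar position, in days, so cross-year comparisons are leap-year
#' safe), the mean of the per-plot ranges, and per-site across-year range
#' and mean day of year.
#'
#' @param obs data.frame of observations with `plot_id`, `date` and
#'   optionally `site` (defaults to one site).
#' @return list with `per_plot` (data.frame `plot_id,n,range_days`),
#'   `mean_plot_range_days`, `largest_plot_range_days`, and `per_site`
#'   (data.frame `site,n,range_days,mean_doy`).
#' @examples
#' observation_stats(observed_budbreak())
#' @export
observation_stats <- function(obs) {
  stopifnot(nrow(obs) >= 1, all(c("plot_id", "date") %in% names(obs)))
  if (!"site" %in% names(obs)) obs$site <- "site"
  pos <- month_day_position(obs$date)
  per_plot <- do.call(rbind, lapply(split(seq_len(nrow(obs)), obs$plot_id),
    function(i) data.frame(plot_id = obs$plot_id[i[1]], n = length(i),
                           range_days = max(pos[i]) - min(pos[i]))))
  per_site <- do.call(rbind, lapply(split(seq_len(nrow(obs)), obs$site),
    function(i) data.frame(site = obs$site[i[1]], n = length(i),
                           range_days = max(pos[i]) - min(pos[i]),
                           mean_doy = mean(pos[i]))))
  rownames(per_plot) <- rownames(per_site) <- NULL
  list(per_plot = per_plot,
       mean_plot_range_days = mean(per_plot$range_days),
       largest_plot_range_days = max(per_plot$range_days),
       per_site = per_site)
}
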