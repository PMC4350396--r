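#' Pipeline configuration
#'
#' Collects everything one full analysis run needs: input paths, model
#' kind, calibration settings, the offset window, reconstruction years and
#' the trend horizon. Either `growth_csv` (per-tree measurements, from
#' which observed dates are derived) or `obs_csv` (observed dates supplied
#' directly) must be given. `station_csv` is optional; when present, the
#' station record is offset-adjusted against the site record over
#' `offset_months` of the calibration years and used for the
#' reconstruction, otherwise the site record itself is used.
#'
#' @param temps_csv daily site temperatures (`date,temp_c`).
#' @param growth_csv growth measurements
#'   (`plot_id,tree_id,date,cum_length_mm`), or `NULL`.
#' @param obs_csv observed bud-break dates (`plot_id,year,date,doy`), or
#'   `NULL`.
#' @param station_csv long station record for the reconstruction, or
#'   `NULL`.
#' @param kind model kind, `"IA"` or `"DL"`.
#' @param ga a [ga_config].
#' @param offset_months months of the offset window (default April-May).
#' @param recon_years integer years to reconstruct (default: the station
#'   or site record's full span of complete bud-break windows).
#' @param horizon_years trend horizon (days of implied change are
#'   `slope * horizon`).
#' @param seed integer seed recorded in all outputs and used for every
#'   stochastic stage.
#' @export
pipeline_config <- function(temps_csv, growth_csv = NULL, obs_csv = NULL,
                            station_csv = NULL, kind = c("DL", "IA"),
                            ga = ga_config(), offset_months = c(4L, 5L),
                            recon_years = NULL, horizon_years = 100,
                            seed = 1) {
  kind <- match.arg(kind)
  if (is.null(growth_csv) && is.null(obs_csv)) {
    stop("one of `growth_csv` or `obs_csv` is required", call. = FALSE)
  }
  structure(list(temps_csv = temps_csv, growth_csv = growth_csv,
                 obs_csv = obs_csv, station_csv = station_csv, kind = kind,
                 ga = ga, offset_months = as.integer(offset_months),
                 recon_years = recon_years,
                 horizon_years = as.integer(horizon_years),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full bud-break analysis pipeline
#'
#' Executes the four stages in order -- derive observed dates, calibrate
#' the model, reconstruct the bud-break series, fit the AR-error trend --
#' and writes each stage's artifact plus a run manifest (inputs with
#' hashes, seed, stage list, package version) into `out_dir`. Stage
#' failures propagate as errors naming the stage; artifacts of completed
#' stages are retained.
#'
#' @param config a [pipeline_config].
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the stage results (`observations`,
#'   `calibration`, `reconstruction`, `trend`) and `artifacts` (paths).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("temps_csv", "growth_csv", "obs_csv", "station_csv")) {
    p <- config[[f]]
    if (!is.null(p) && !file.exists(p)) {
      stop("pipeline input `", f, "` not found: ", p, call. = FALSE)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  artifacts <- character(0)

  temps <- stage("read-temps", read_daily_temps(config$temps_csv))

  obs <- stage("derive-obs", {
    if (!is.null(config$growth_csv)) {
      g <- read_growth_csv(config$growth_csv)
      g$year <- format(g$date, "%Y")
      parts <- split(g, paste(g$plot_id, g$year))
      as_observation_table(lapply(parts, function(m) {
        derive_budbreak_date(m[c("plot_id", "tree_id", "date",
                                 "cum_length_mm")])
      }))
    } else {
      read_observations_csv(config$obs_csv)
    }
  })
  obs_path <- file.path(out_dir, "observations.csv")
  write_observations_csv(obs, obs_path)
  artifacts <- c(artifacts, obs_path)

  cfg_ga <- config$ga
  cfg_ga$rng_seed <- config$seed
  cal <- stage("calibrate",
               calibrate_model(config$kind, temps, obs,
                               bounds = parameter_bounds(config$kind),
                               config = cfg_ga))
  cal_path <- file.path(out_dir, "calibration.json")
  write_calibration(cal, cal_path)
  artifacts <- c(artifacts, cal_path)

  recon <- stage("reconstruct", {
    if (!is.null(config$station_csv)) {
      station <- read_daily_temps(config$station_csv)
      adj <- compute_offset(temps, station, months = config$offset_months,
                            years = unique(obs$year))
      driver <- station
    } else {
      station <- temps
      adj <- NULL
      driver <- temps
    }
    yrs <- config$recon_years
    if (is.null(yrs)) {
      span <- as.integer(format(range(driver$date), "%Y"))
      yrs <- seq(span[1] + 1L, span[2])  # first year lacks a chilling autumn
      yrs <- yrs[as.Date(sprintf("%d-06-30", yrs)) <= max(driver$date)]
    }
    reconstruct_budbreak(driver, adj, cal$model, yrs)
  })
  recon_path <- file.path(out_dir, "reconstruction.csv")
  write_reconstruction_csv(recon, recon_path)
  artifacts <- c(artifacts, recon_path)

  trend <- stage("trend", {
    with_seed(config$seed,
              fit_trend(recon, horizon_years = config$horizon_years))
  })
  trend_path <- file.path(out_dir, "trend.json")
  write_trend(trend, trend_path)
  artifacts <- c(artifacts, trend_path)

  inputs <- Filter(Negate(is.null),
                   config[c("temps_csv", "growth_csv", "obs_csv",
                            "station_csv")])
  manifest <- list(
    package = "budbreakr",
    version = as.character(utils::packageVersion("budbreakr")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    kind = config$kind,
    stages = c("derive-obs", "calibrate", "reconstruct", "trend"),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    artifacts = lapply(artifacts, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  artifacts <- c(artifacts, manifest_path)

  invisible(list(observations = obs, calibration = cal,
                 reconstruction = recon, trend = trend,
                 artifacts = artifacts))
}
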