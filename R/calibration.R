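#' Published parameter bounds for calibration
#'
#' Bounds and starting values for the optimizable parameters of each model
#' kind. Forcing: `fu_crit` in \[0, 250\] (start 50), `a` in \[15, 40\]
#' (start 28.361), `b` in \[0.01, 1.0\] (start 0.185), `c` in \[5, 30\]
#' (start 18.431). Kind `"IA"` adds `cu_crit` in \[0, 120\] (start 20)
#' with the rest-period start fixed at September 1. Kind `"DL"` adds the
#' forcing release day of year in \[1, 151\] (January 1 to May 31, start
#' March 15).
#'
#' @param kind `"IA"` or `"DL"`.
#' @return A `parameter_bounds` data.frame with columns `parameter`,
#'   `default`, `min`, `max`, `integer`; kind and the fixed rest-start
#'   date are carried as attributes.
#' @export
parameter_bounds <- function(kind = c("IA", "DL")) {
  kind <- match.arg(kind)
  b <- data.frame(
    parameter = c("a", "b", "c", "fu_crit"),
    default = c(28.361, 0.185, 18.431, 50),
    min = c(15, 0.01, 5, 0),
    max = c(40, 1.0, 30, 250),
    integer = FALSE)
  extra <- if (kind == "IA") {
    data.frame(parameter = "cu_crit", default = 20, min = 0, max = 120,
               integer = FALSE)
  } else {
    data.frame(parameter = "forcing_start_doy", default = 74, min = 1,
               max = 151, integer = TRUE)
  }
  out <- rbind(b, extra)
  if (any(out$min > out$max)) stop("infeasible bounds", call. = FALSE)
  attr(out, "kind") <- kind
  attr(out, "rest_start") <- "09-01"
  class(out) <- c("parameter_bounds", "data.frame")
  out
}

#' Genetic-algorithm configuration
#'
#' A generational GA with tournament selection, uniform crossover,
#' Gaussian mutation scaled to 10 % of each bound width, bound clipping
#' and elitism. Stopping is deterministic: the run ends after
#' `stall_generations` generations without an improvement of the
#' best-so-far RMSE larger than `convergence_tol`, or at
#' `max_generations`.
#'
#' @param population_size individuals per generation (at least 2).
#' @param mutation_rate per-gene mutation probability.
#' @param crossover_rate probability a child is a uniform mix of both
#'   parents rather than a copy of the first.
#' @param tournament_size selection tournament size.
#' @param elitism number of best individuals copied unchanged.
#' @param convergence_tol RMSE improvement (days) counted as progress.
#' @param stall_generations stopping patience.
#' @param max_generations hard cap on generations.
#' @param rng_seed integer seed; identical seeds give identical results.
#' @export
ga_config <- function(population_size = 250, mutation_rate = 0.1,
                      crossover_rate = 0.7, tournament_size = 3,
                      elitism = 1, convergence_tol = 1e-4,
                      stall_generations = 50, max_generations = 500,
                      rng_seed = NULL) {
  stopifnot(population_size >= 2, mutation_rate > 0, mutation_rate < 1,
            crossover_rate > 0, crossover_rate <= 1, convergence_tol > 0,
            stall_generations >= 1, max_generations >= 1)
  structure(list(population_size = as.integer(population_size),
                 mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate,
                 tournament_size = as.integer(tournament_size),
                 elitism = as.integer(elitism),
                 convergence_tol = convergence_tol,
                 stall_generations = as.integer(stall_generations),
                 max_generations = as.integer(max_generations),
                 rng_seed = rng_seed),
            class = "ga_config")
}

#' RMSE between predicted and observed bud-break dates
#'
#' Root mean square error in days of signed differences predicted minus
#' observed. A missing prediction (forcing requirement never reached) is
#' penalized as the end of the accumulation window (June 30 of the
#' observation year by default), which keeps the calibration objective
#' finite.
#'
#' @param predicted `Date` vector, `NA` allowed.
#' @param observed `Date` vector, same length.
#' @param window_end `Date` vector substituted for missing predictions;
#'   default June 30 of each observed year.
#' @return RMSE in days.
#' @examples
#' rmse_days(as.Date("2001-05-10") + c(1, 2, 2), rep(as.Date("2001-05-10"), 3))
#' @export
rmse_days <- function(predicted, observed, window_end = NULL) {
  observed <- as.Date(observed)
  predicted <- as.Date(predicted)
  if (length(predicted) != length(observed)) {
    stop("`predicted` and `observed` must have equal length", call. = FALSE)
  }
  if (length(observed) == 0) stop("empty observation list", call. = FALSE)
  if (is.null(window_end)) {
    window_end <- as.Date(sprintf("%s-06-30", format(observed, "%Y")))
  }
  miss <- is.na(predicted)
  predicted[miss] <- window_end[miss]
  d <- as.numeric(predicted - observed)
  sqrt(mean(d^2))
}

# Precompute per-year accumulation windows for the fast calibration
# objective: window temperatures, window start date, and (IA) the
# cumulative chilling curve, which depends only on temperature.
precompute_year_data <- function(temps, kind, years, rest_start = "09-01") {
  lapply(years, function(y) {
    start <- if (kind == "IA") rest_start_date(rest_start, y)
             else as.Date(sprintf("%d-01-01", y))
    end <- as.Date(sprintf("%d-06-30", y))
    if (nrow(temps) == 0 || temps$date[1] > start ||
        temps$date[nrow(temps)] < end) {
      stop("temperature series does not cover the window for year ", y,
           call. = FALSE)
    }
    tv <- temps$temp_c[temps$date >= start & temps$date <= end]
    if (anyNA(tv)) {
      stop("temperature gap inside the accumulation window for year ", y,
           call. = FALSE)
    }
    list(year = y, start = start, end = end, tv = tv,
         cu_cum = if (kind == "IA") cumsum(chilling_rate(tv)))
  })
}

# Predicted bud-break date for one precomputed year; NA when the forcing
# requirement is not reached by the window end.
fast_predict_date <- function(yd, kind, a, b, c, fu_crit, cu_crit = NULL,
                              start_doy = NULL) {
  n <- length(yd$tv)
  from <- if (kind == "IA") {
    if (cu_crit <= 0) 1L else {
      ci <- match(TRUE, yd$cu_cum >= cu_crit)
      if (is.na(ci)) return(as.Date(NA))
      ci + 1L
    }
  } else {
    as.integer(start_doy)  # window starts January 1, so index == day of year
  }
  if (is.na(from) || from > n) return(as.Date(NA))
  tv <- yd$tv[from:n]
  fr <- a / (1 + exp(-b * (tv - c)))
  fr[tv <= 0] <- 0
  fu <- cumsum(fr)
  i <- match(TRUE, fu >= fu_crit)
  if (is.na(i)) return(as.Date(NA))
  yd$start + (from + i - 2L)
}

theta_to_model <- function(theta, kind, rest_start = "09-01") {
  fp <- forcing_params(theta[["a"]], theta[["b"]], theta[["c"]],
                       theta[["fu_crit"]])
  if (kind == "IA") {
    model_spec("IA", fp, chilling = chilling_params(theta[["cu_crit"]],
                                                    rest_start))
  } else {
    model_spec("DL", fp, forcing_start_doy = theta[["forcing_start_doy"]])
  }
}

#' Calibrate a bud-break model against observations
#'
#' Minimizes the RMSE between predicted and observed bud-break dates over
#' the bounded parameter space with a genetic algorithm. All observations
#' of one site are pooled into a single objective. The starting values of
#' [parameter_bounds()] are seeded into the initial population, so the
#' returned fit is never worse than the default parameterization. Between
#' candidates of equal RMSE the smaller `fu_crit` (then smaller `cu_crit`)
#' is preferred.
#'
#' @param kind `"IA"` or `"DL"`.
#' @param temps [daily_temps] covering every observation year's
#'   accumulation window without gaps.
#' @param observations observation table (see [as_observation_table()])
#'   with `year` and `date`.
#' @param bounds a [parameter_bounds] object matching `kind`.
#' @param config a [ga_config].
#' @return A `calibration_result`: list with `model` (the best
#'   [model_spec]), `rmse_days`, `generations_run`, `history` (best-so-far
#'   RMSE per generation), `residuals` (data.frame
#'   `year,observed,predicted,residual_days`), `config`.
#' @export
calibrate_model <- function(kind = c("IA", "DL"), temps, observations,
                            bounds = parameter_bounds(kind),
                            config = ga_config()) {
  kind <- match.arg(kind)
  stopifnot(inherits(bounds, "parameter_bounds"),
            identical(attr(bounds, "kind"), kind))
  obs <- as_observation_table(observations)
  if (nrow(obs) == 0) stop("no observations", call. = FALSE)
  rest_start <- attr(bounds, "rest_start")
  ydat <- precompute_year_data(temps, kind, obs$year, rest_start)
  win_end <- as.Date(sprintf("%d-06-30", obs$year))
  par_names <- bounds$parameter
  lo <- bounds$min
  hi <- bounds$max
  is_int <- bounds$integer
  k <- length(par_names)

  clip <- function(th) {
    th <- pmin(pmax(th, lo), hi)
    th[is_int] <- round(th[is_int])
    th
  }
  predict_all <- function(th) {
    names(th) <- par_names
    as.Date(vapply(ydat, function(yd) {
      as.numeric(fast_predict_date(
        yd, kind, th[["a"]], th[["b"]], th[["c"]], th[["fu_crit"]],
        cu_crit = if (kind == "IA") th[["cu_crit"]],
        start_doy = if (kind == "DL") th[["forcing_start_doy"]]))
    }, numeric(1)), origin = "1970-01-01")
  }
  objective <- function(th) rmse_days(predict_all(th), obs$date, win_end)
  # lexicographic fitness: RMSE, then parsimony in fu_crit and cu_crit
  tie_key <- function(th) {
    c(th[match("fu_crit", par_names)],
      if (kind == "IA") th[match("cu_crit", par_names)] else 0)
  }
  better <- function(f1, k1, f2, k2) {
    if (f1 != f2) return(f1 < f2)
    if (k1[1] != k2[1]) return(k1[1] < k2[1])
    k1[2] < k2[2]
  }

  if (!is.null(config$rng_seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    }, add = TRUE)
    set.seed(config$rng_seed)
  }

  np <- config$population_size
  pop <- t(vapply(seq_len(np), function(i) clip(stats::runif(k, lo, hi)),
                  numeric(k)))
  pop[1, ] <- clip(bounds$default)
  fit <- apply(pop, 1, objective)

  best_i <- order(fit, pop[, match("fu_crit", par_names)])[1]
  best_theta <- pop[best_i, ]
  best_fit <- fit[best_i]
  best_key <- tie_key(best_theta)
  history <- numeric(0)
  stall <- 0L
  gen <- 0L
  mut_sd <- 0.1 * (hi - lo)

  while (gen < config$max_generations && stall < config$stall_generations) {
    gen <- gen + 1L
    ord <- order(fit)
    elite <- pop[ord[seq_len(config$elitism)], , drop = FALSE]
    children <- matrix(NA_real_, nrow = np - config$elitism, ncol = k)
    for (i in seq_len(nrow(children))) {
      t1 <- sample.int(np, config$tournament_size)
      p1 <- pop[t1[which.min(fit[t1])], ]
      t2 <- sample.int(np, config$tournament_size)
      p2 <- pop[t2[which.min(fit[t2])], ]
      child <- p1
      if (stats::runif(1) < config$crossover_rate) {
        take2 <- stats::runif(k) < 0.5
        child[take2] <- p2[take2]
      }
      mut <- stats::runif(k) < config$mutation_rate
      child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, mut_sd[mut])
      children[i, ] <- clip(child)
    }
    pop <- rbind(elite, children)
    fit <- apply(pop, 1, objective)
    for (i in seq_len(np)) {
      ki <- tie_key(pop[i, ])
      if (better(fit[i], ki, best_fit, best_key)) {
        if (best_fit - fit[i] > config$convergence_tol) stall <- -1L
        best_fit <- fit[i]
        best_theta <- pop[i, ]
        best_key <- ki
      }
    }
    stall <- stall + 1L
    history <- c(history, best_fit)
  }

  names(best_theta) <- par_names
  model <- theta_to_model(best_theta, kind, rest_start)
  pred <- predict_all(best_theta)
  pred_pen <- pred
  pred_pen[is.na(pred_pen)] <- win_end[is.na(pred)]
  res <- data.frame(year = obs$year, observed = obs$date, predicted = pred,
                    residual_days = as.numeric(pred_pen - obs$date))
  structure(list(kind = kind, model = model, rmse_days = best_fit,
                 generations_run = gen, history = history, residuals = res,
                 config = config),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> kind ", x$kind, ", RMSE ",
      sprintf("%.3f", x$rmse_days), " days over ", nrow(x$residuals),
      " observation(s), ", x$generations_run, " generation(s)\n", sep = "")
  print(x$model)
  invisible(x)
}

#' @rdname calibrate_model
#' @param x a `calibration_result`.
#' @param path JSON file path.
#' @export
write_calibration <- function(x, path) {
  stopifnot(inherits(x, "calibration_result"))
  f <- x$model$forcing
  obj <- list(
    kind = x$kind,
    model = c(list(kind = x$kind, a = f$a, b = f$b, c = f$c,
                   fu_crit = f$fu_crit),
              if (x$kind == "IA") list(cu_crit = x$model$chilling$cu_crit,
                                       rest_start = x$model$chilling$rest_start)
              else list(forcing_start_doy = x$model$forcing_start_doy)),
    rmse_days = x$rmse_days,
    generations_run = x$generations_run,
    history = x$history,
    residuals = data.frame(year = x$residuals$year,
                           observed = format(x$residuals$observed),
                           predicted = ifelse(is.na(x$residuals$predicted), "",
                                              format(x$residuals$predicted)),
                           residual_days = x$residuals$residual_days),
    config = unclass(x$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
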