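test_that("RMSE handles exact fits, constant offsets, and penalties", {
  base <- as.Date("2001-05-10") + 0:2
  expect_equal(rmse_days(base, base), 0)
  expect_equal(rmse_days(base + c(3, -3, 3), base), 3)
  expect_equal(rmse_days(base + c(1, 2, 2), base), sqrt(9 / 3))
  expect_error(rmse_days(as.Date(character()), as.Date(character())), "empty")
  # a missing prediction is scored as the window end (June 30)
  obs <- as.Date("2001-05-10")
  expect_equal(rmse_days(as.Date(NA), obs),
               as.numeric(as.Date("2001-06-30") - obs))
})

test_that("bounds collapsed to a point return exactly that parameter set", {
  fx <- recovery_fixture(n_years = 3)
  b <- parameter_bounds("DL")
  b$min <- b$default
  b$max <- b$default
  r <- calibrate_model("DL", fx$temps, fx$obs, bounds = b,
                       config = ga_config(population_size = 10,
                                          max_generations = 3,
                                          stall_generations = 2,
                                          rng_seed = 1))
  expect_equal(r$model$forcing$a, 28.361)
  expect_equal(r$model$forcing$fu_crit, 50)
  expect_equal(r$model$forcing_start_doy, 74L)
  # and the RMSE is that of the default model
  pred <- as.Date(vapply(fx$obs$year, function(y)
    format(predict_budbreak(fx$temps, r$model, y)$date), character(1)))
  expect_equal(r$rmse_days, rmse_days(pred, fx$obs$date))
})

test_that("calibration is deterministic under a fixed seed", {
  fx <- recovery_fixture(n_years = 5)
  cfg <- ga_config(population_size = 40, max_generations = 30,
                   stall_generations = 10, rng_seed = 99)
  r1 <- calibrate_model("DL", fx$temps, fx$obs, config = cfg)
  r2 <- calibrate_model("DL", fx$temps, fx$obs, config = cfg)
  expect_identical(r1$rmse_days, r2$rmse_days)
  expect_identical(r1$history, r2$history)
  expect_equal(r1$model, r2$model)
})

test_that("best-so-far RMSE never increases and bounds are respected", {
  fx <- recovery_fixture(n_years = 5)
  r <- calibrate_model("DL", fx$temps, fx$obs,
                       config = ga_config(population_size = 40,
                                          max_generations = 40,
                                          stall_generations = 15,
                                          rng_seed = 3))
  expect_true(all(diff(r$history) <= 0))
  b <- parameter_bounds("DL")
  f <- r$model$forcing
  got <- c(f$a, f$b, f$c, f$fu_crit, r$model$forcing_start_doy)
  expect_true(all(got >= b$min & got <= b$max))
  expect_equal(nrow(r$residuals), nrow(fx$obs))
})

test_that("noise-free synthetic observations are recovered within a day", {
  fx <- recovery_fixture(n_years = 9)
  r <- calibrate_model("DL", fx$temps, fx$obs,
                       config = ga_config(population_size = 100,
                                          max_generations = 200,
                                          rng_seed = 17))
  expect_lte(r$rmse_days, 1)
  # a different seed also lands at a good date fit
  r2 <- calibrate_model("DL", fx$temps, fx$obs,
                        config = ga_config(population_size = 100,
                                           max_generations = 200,
                                           rng_seed = 18))
  expect_lte(r2$rmse_days, 1)
})

test_that("the sequential chilling model calibrates too", {
  cl <- subarctic_series(2000:2008, 11)
  truth <- model_spec("IA", forcing_params(22, 0.5, 8, 150),
                      chilling = chilling_params(25))
  yrs <- 2001:2007
  obs <- data.frame(plot_id = "p1", year = yrs,
                    date = as.Date(vapply(yrs, function(y)
                      format(predict_budbreak(cl, truth, y)$date),
                      character(1))))
  r <- calibrate_model("IA", cl, obs,
                       config = ga_config(population_size = 80,
                                          max_generations = 120,
                                          stall_generations = 30,
                                          rng_seed = 5))
  expect_lte(r$rmse_days, 1)
  expect_equal(r$model$chilling$rest_start, "09-01")
})

test_that("calibration results serialize to JSON", {
  fx <- recovery_fixture(n_years = 3)
  r <- calibrate_model("DL", fx$temps, fx$obs,
                       config = ga_config(population_size = 20,
                                          max_generations = 10,
                                          stall_generations = 5,
                                          rng_seed = 2))
  p <- file.path(tempdir(), "cal.json")
  write_calibration(r, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$rmse_days, r$rmse_days)
  expect_equal(back$model$kind, "DL")
  expect_equal(length(back$history), r$generations_run)
})
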