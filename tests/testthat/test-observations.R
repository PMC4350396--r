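make_plot <- function(trees) {
  # trees: named list tree_id -> data.frame(date, cum_length_mm)
  do.call(rbind, lapply(names(trees), function(id) {
    data.frame(plot_id = "p1", tree_id = id, date = trees[[id]]$date,
               cum_length_mm = trees[[id]]$cum_length_mm)
  }))
}

test_that("interpolated criteria date matches hand computation", {
  # 5 trees at 0 mm on May 1 and 7 mm on May 8 (1 mm/day), totals 100 mm
  d <- as.Date(c("2001-05-01", "2001-05-08", "2001-09-01"))
  trees <- setNames(rep(list(data.frame(date = d,
                                        cum_length_mm = c(0, 7, 100))), 5),
                    paste0("t", 1:5))
  obs <- derive_budbreak_date(make_plot(trees))
  expect_equal(obs$date, as.Date("2001-05-02"))
  expect_equal(obs$status, "detected")
  expect_equal(obs$year, 2001L)
})

test_that("criteria already met at first measurement are left-censored", {
  d <- as.Date(c("2001-05-01", "2001-09-01"))
  trees <- setNames(rep(list(data.frame(date = d,
                                        cum_length_mm = c(5, 100))), 4),
                    paste0("t", 1:4))
  obs <- derive_budbreak_date(make_plot(trees))
  expect_equal(obs$date, as.Date("2001-05-01"))
  expect_equal(obs$status, "left_censored")
})

test_that("'more than half' is strict and failures are explicit", {
  d <- as.Date(c("2001-05-01", "2001-06-01", "2001-09-01"))
  grower <- data.frame(date = d, cum_length_mm = c(0, 50, 100))
  idle <- data.frame(date = d, cum_length_mm = c(0, 0, 0))
  four_of_ten <- c(rep(list(grower), 4), rep(list(idle), 6))
  obs <- derive_budbreak_date(make_plot(setNames(four_of_ten, paste0("t", 1:10))))
  expect_equal(obs$status, "not_detected")
  expect_true(is.na(obs$date))
  # exactly half does not qualify either
  five_of_ten <- c(rep(list(grower), 5), rep(list(idle), 5))
  obs5 <- derive_budbreak_date(make_plot(setNames(five_of_ten, paste0("t", 1:10))))
  expect_equal(obs5$status, "not_detected")
  # six of ten does
  six_of_ten <- c(rep(list(grower), 6), rep(list(idle), 4))
  obs6 <- derive_budbreak_date(make_plot(setNames(six_of_ten, paste0("t", 1:10))))
  expect_equal(obs6$status, "detected")
})

test_that("non-monotone growth names the offending tree", {
  d <- as.Date(c("2001-05-01", "2001-05-08", "2001-09-01"))
  trees <- list(t1 = data.frame(date = d, cum_length_mm = c(0, 7, 100)),
                t2 = data.frame(date = d, cum_length_mm = c(5, 3, 100)))
  expect_error(derive_budbreak_date(make_plot(trees)), "t2")
})

test_that("derivation is invariant to tree relabeling", {
  set.seed(21)
  cl <- subarctic_series(2000:2002, 13)
  sim <- simulate_observations(cl, obs_gen_params(laanila_dl_model(),
                                                  rng_seed = 5), 2001)
  m <- sim$measurements
  a <- derive_budbreak_date(m)
  m2 <- m
  m2$tree_id <- sprintf("relabel_%s", m$tree_id)
  b <- derive_budbreak_date(m2)
  expect_equal(a$date, b$date)
})

test_that("tightening thresholds never gives an earlier date", {
  set.seed(22)
  cl <- subarctic_series(2000:2003, 17)
  sim <- simulate_observations(cl, obs_gen_params(laanila_dl_model(),
                                                  rng_seed = 6), 2001:2003)
  for (y in 2001:2003) {
    m <- sim$measurements[format(sim$measurements$date, "%Y") == y, ]
    base <- derive_budbreak_date(m)
    for (rule in list(budbreak_rule(min_tree_mm = 3),
                      budbreak_rule(tree_fraction = 0.8),
                      budbreak_rule(min_plot_fraction = 0.05))) {
      tight <- derive_budbreak_date(m, rule)
      if (!is.na(base$date) && !is.na(tight$date)) {
        expect_true(tight$date >= base$date)
      }
    }
  }
})

test_that("derivation agrees with the brute-force daily evaluator", {
  set.seed(23)
  cl <- subarctic_series(2000:2006, 19)
  n_checked <- 0
  for (seed in 1:12) {
    sim <- simulate_observations(
      cl, obs_gen_params(laanila_dl_model(), n_trees = sample(4:8, 1),
                         interval_days = sample(c(3, 7, 10), 1),
                         noise_sd_mm = runif(1, 0, 1), rng_seed = 300 + seed),
      sample(2001:2006, 2))
    for (y in unique(sim$truth$year)) {
      m <- sim$measurements[format(sim$measurements$date, "%Y") == y, ]
      got <- derive_budbreak_date(m)
      expect_equal(got$date, oracle_derive_date(m),
                   info = sprintf("seed %d year %d", seed, y))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 20)
})

test_that("the result is always inside the measurement span or censored", {
  set.seed(24)
  cl <- subarctic_series(2000:2002, 29)
  sim <- simulate_observations(cl, obs_gen_params(laanila_dl_model(),
                                                  noise_sd_mm = 1,
                                                  rng_seed = 8), 2001:2002)
  for (y in 2001:2002) {
    m <- sim$measurements[format(sim$measurements$date, "%Y") == y, ]
    o <- derive_budbreak_date(m)
    if (!is.na(o$date)) {
      expect_true(o$date >= min(m$date) && o$date <= max(m$date))
    }
  }
})

test_that("observation summary statistics use month-day alignment", {
  one <- data.frame(plot_id = "p", date = as.Date("2001-05-10"))
  expect_equal(observation_stats(one)$per_plot$range_days, 0)

  obs <- observed_budbreak()
  st <- observation_stats(obs)
  expect_equal(st$largest_plot_range_days, 16)
  l1 <- st$per_plot[st$per_plot$plot_id == "laanila_1", ]
  expect_equal(l1$range_days, 16)
  expect_equal(nrow(st$per_plot), 5)
  expect_equal(sum(st$per_plot$n), 15)
  # the southern site starts growth earlier on average
  ps <- st$per_site
  expect_lt(ps$mean_doy[ps$site == "vanttauskoski"],
            ps$mean_doy[ps$site == "laanila"])
})

test_that("observation tables reject duplicate plot-years and round trip", {
  obs <- observed_budbreak()
  tab <- as_observation_table(obs[c("plot_id", "year", "date")])
  expect_equal(nrow(tab), 15)
  p <- file.path(tempdir(), "obs.csv")
  write_observations_csv(tab, p)
  expect_equal(read_observations_csv(p)$doy, tab$doy)
  dup <- rbind(obs, obs[1, ])
  expect_error(as_observation_table(dup[c("plot_id", "year", "date")]),
               "plot-year")
})
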