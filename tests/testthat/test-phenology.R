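test_that("forcing rate follows the sigmoid with a hard zero branch", {
  p <- forcing_params()
  expect_equal(forcing_rate(-5, p), 0)
  expect_equal(forcing_rate(0, p), 0)
  expect_gt(forcing_rate(1e-9, p), 0)
  # midpoint: half the asymptote at the inflection temperature
  expect_equal(forcing_rate(p$c, p), p$a / 2)
  expect_equal(forcing_rate(4, forcing_params(a = 10, b = 0.5, c = 4)), 5)
})

test_that("forcing rate at 30 C matches direct evaluation", {
  expect_equal(forcing_rate(30, forcing_params()),
               28.361 / (1 + exp(-0.185 * (30 - 18.431))),
               tolerance = 1e-12)
  expect_equal(round(forcing_rate(30, forcing_params()), 2), 25.38)
})

test_that("forcing rate is non-decreasing in temperature and below a", {
  set.seed(101)
  p <- forcing_params()
  temps <- sort(runif(1000, -30, 40))
  r <- forcing_rate(temps, p)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r >= 0 & r < p$a))
})

test_that("chilling rate is the clamped triangular response", {
  expect_equal(chilling_rate(-10), 0)
  expect_equal(chilling_rate(15), 0)
  expect_equal(chilling_rate(0), 0.506)
  expect_equal(chilling_rate(3.5), 0.159 * 3.5 + 0.506)  # lower branch at 3.5
  expect_equal(chilling_rate(3.5), 1.0625)
  # printed coefficients would go negative just above -3.4; clamped to 0
  expect_equal(chilling_rate(-3.3), 0)
  set.seed(102)
  temps <- runif(500, -20, 20)
  r <- chilling_rate(temps)
  expect_true(all(r >= 0))
  expect_true(all(r[temps <= -3.4 | temps > 10.4] == 0))
  # unimodal with the maximum at the breakpoint
  expect_true(all(r <= chilling_rate(3.5)))
})

test_that("constant-temperature prediction matches the ceiling closed form", {
  for (case in list(c(124.2, 10), c(50, 25), c(200, 5.2), c(10, 1))) {
    fu_crit <- case[1]; temp <- case[2]
    m <- model_spec("DL", forcing_params(19.8, 0.73, 6.1, fu_crit),
                    forcing_start_doy = 89)
    s <- constant_series(temp, 2001)
    r <- forcing_rate(temp, m$forcing)
    pred <- predict_budbreak(s, m, 2001)
    expected_day <- ceiling(fu_crit / r)  # start day counts as day 1
    if (expected_day <= as.numeric(as.Date("2001-06-30") - as.Date("2001-03-30")) + 1) {
      expect_equal(as.numeric(pred$date - as.Date("2001-03-30")) + 1,
                   expected_day)
    } else {
      expect_true(is.na(pred$date))
    }
  }
})

test_that("sub-zero springs never accumulate forcing", {
  s <- constant_series(-2, 2001)
  pred <- predict_budbreak(s, laanila_dl_model(), 2001)
  expect_true(is.na(pred$date))
  expect_equal(pred$forcing_attained, 0)
})

test_that("fixed-date release at constant 10 C reproduces the oracle date", {
  s <- constant_series(10, 2001)
  m <- laanila_dl_model()
  pred <- predict_budbreak(s, m, 2001)
  expect_equal(pred$date, oracle_predict_date(s, m, 2001))
  expect_equal(pred$date, as.Date("2001-04-05"))
})

test_that("zero chilling requirement reduces the sequential model to fixed-date", {
  fp <- forcing_params(22, 0.5, 8, 150)
  ia <- model_spec("IA", fp, chilling = chilling_params(0, rest_start = "01-15"))
  dl <- model_spec("DL", fp, forcing_start_doy = 15)
  for (seed in 1:5) {
    s <- subarctic_series(2000:2001, seed)
    expect_equal(predict_budbreak(s, ia, 2001)$date,
                 predict_budbreak(s, dl, 2001)$date)
  }
})

test_that("prediction agrees with the brute-force day loop on random series", {
  set.seed(103)
  for (i in 1:15) {
    s <- subarctic_series(2000:2001, seed = 1000 + i)
    mdl <- model_spec("DL",
                      forcing_params(runif(1, 15, 40), runif(1, 0.05, 1),
                                     runif(1, 5, 30), runif(1, 20, 250)),
                      forcing_start_doy = sample(30:140, 1))
    mia <- model_spec("IA",
                      forcing_params(runif(1, 15, 40), runif(1, 0.05, 1),
                                     runif(1, 5, 30), runif(1, 20, 250)),
                      chilling = chilling_params(runif(1, 0, 45)))
    for (m in list(mdl, mia)) {
      expect_equal(predict_budbreak(s, m, 2001)$date,
                   oracle_predict_date(s, m, 2001),
                   info = sprintf("kind %s seed %d", m$kind, i))
    }
  }
})

test_that("warmer springs and lower requirements never delay bud break", {
  set.seed(104)
  m <- laanila_dl_model()
  for (i in 1:10) {
    s <- subarctic_series(2000:2001, seed = 2000 + i)
    warm <- s
    warm$temp_c <- warm$temp_c + runif(nrow(s), 0, 2)
    d0 <- predict_budbreak(s, m, 2001)$date
    d1 <- predict_budbreak(warm, m, 2001)$date
    if (!is.na(d0)) expect_true(!is.na(d1) && d1 <= d0)
    m_low <- model_spec("DL", forcing_params(19.8, 0.73, 6.1, 80),
                        forcing_start_doy = 89)
    d2 <- predict_budbreak(s, m_low, 2001)$date
    if (!is.na(d0)) expect_true(!is.na(d2) && d2 <= d0)
  }
})

test_that("gaps inside the consumed window are fatal and named", {
  s <- subarctic_series(2000:2001, seed = 9,
                        gaps = list(c("2001-04-10", "2001-04-12")))
  expect_error(predict_budbreak(s, laanila_dl_model(), 2001), "2001-04-10")
  # a gap before the release date is never consumed by the DL model
  s2 <- subarctic_series(2000:2001, seed = 9,
                         gaps = list(c("2001-02-01", "2001-02-10")))
  expect_s3_class(predict_budbreak(s2, laanila_dl_model(), 2001),
                  "budbreak_prediction")
  short <- constant_series(10, 2001)
  expect_error(predict_budbreak(short, laanila_dl_model(), 2002), "cover")
})

test_that("accumulation curves are monotone and consistent with prediction", {
  s <- subarctic_series(2000:2001, seed = 31)
  m <- model_spec("IA", forcing_params(22, 0.5, 8, 150),
                  chilling = chilling_params(25))
  ac <- accumulation_curves(s, m, 2001)
  expect_true(all(diff(ac$cu_cum) >= 0))
  expect_true(all(diff(ac$fu_cum) >= 0))
  pred <- predict_budbreak(s, m, 2001)
  expect_equal(ac$fu_cum[nrow(ac)], pred$forcing_attained)
  # chilling stops contributing after the competence date
  after <- ac$date > pred$competence_date
  expect_equal(length(unique(ac$cu_cum[after])), 1L)

  frozen <- constant_series(0, 2001)
  ac0 <- accumulation_curves(frozen, laanila_dl_model(), 2001)
  expect_true(all(ac0$fu_cum == 0))
})

test_that("model specs survive a JSON round trip", {
  p <- file.path(tempdir(), "model.json")
  m1 <- laanila_dl_model()
  write_model_spec(m1, p)
  expect_equal(read_model_spec(p), m1)
  m2 <- model_spec("IA", forcing_params(31.9, 0.53, 7.8, 127.9),
                   chilling = chilling_params(15.4))
  write_model_spec(m2, p)
  expect_equal(read_model_spec(p), m2)
})
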