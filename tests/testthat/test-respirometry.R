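# Trap titration -> CO2, baseline subtraction, accumulation, daily rates.

test_that("titration_to_co2 matches the back-titration formula", {
  expect_equal(titration_to_co2(10, 10, 1), 0)
  expect_equal(titration_to_co2(10, 5, 1), 110)
  expect_equal(titration_to_co2(8.2, 6, 0.5), 24.2)
  # linear in (blank - sample) and in normality
  d <- runif(20, 0, 5)
  n <- runif(20, 0.1, 2)
  expect_equal(titration_to_co2(10 + 2 * d, 10, n),
               2 * titration_to_co2(10 + d, 10, n))
  expect_equal(titration_to_co2(10, 4, 2 * n),
               2 * titration_to_co2(10, 4, n))
  # configurable conversion constant
  expect_equal(titration_to_co2(10, 5, 1, mg_per_meq = 10), 50)
})

test_that("titration_to_co2 rejects invalid records, naming the day", {
  expect_error(titration_to_co2(5, 6, 1, day = 7), "negative CO2.*day 7")
  expect_error(titration_to_co2(10, 5, 0), "normality")
  expect_error(titration_to_co2(10, -1, 1), ">= 0")
})

test_that("microcosm_spec enforces its invariants", {
  sp <- microcosm_spec("d1", "diesel", 2000, 1000, setup = "soil_bed")
  expect_s3_class(sp, "microcosm_spec")
  expect_identical(sp$fuel, "DIESEL")
  expect_error(microcosm_spec("c1", "CONTROL", fuel_mass = 100),
               "if and only if")
  expect_error(microcosm_spec("d1", "DIESEL", fuel_mass = 0),
               "if and only if")
  expect_error(microcosm_spec("d1", "DIESEL", replicate = 0), "replicate")
  expect_error(microcosm_spec("d1", "KEROSENE"))
})

test_that("subtract_baseline floors at zero and keeps raw values", {
  s <- make_series(c(10, 20))
  ctl <- make_series(c(10, 20))
  net <- subtract_baseline(s, ctl)
  expect_equal(net$daily_co2, c(0, 0))
  expect_true(net$baseline_subtracted)

  net <- subtract_baseline(make_series(c(50, 60)), make_series(c(5, 5)))
  expect_equal(net$daily_co2, c(45, 55))

  net <- subtract_baseline(make_series(c(4, 30)), make_series(c(6, 5)))
  expect_equal(net$daily_co2, c(0, 25))
  expect_equal(net$daily_co2_raw, c(-2, 25))
  expect_equal(net$cumulative_co2, c(0, 25))
})

test_that("subtract_baseline requires a common day grid", {
  s <- make_series(c(1, 2, 3), days = c(1, 2, 3))
  ctl <- make_series(c(1, 2), days = c(1, 3))
  expect_error(subtract_baseline(s, ctl), "missing from control: 2")
  # aligning interpolates the control onto the sample grid
  net <- subtract_baseline(s, ctl, align = TRUE)
  expect_equal(net$days, c(1, 2, 3))
})

test_that("accumulate maintains the running-sum invariant", {
  s <- make_series(c(0, 0, 0))
  expect_equal(accumulate(s)$cumulative_co2, c(0, 0, 0))
  s <- make_series(c(10, 20, 5))
  expect_equal(s$cumulative_co2, c(10, 30, 35))
  s$daily_co2 <- c(1, 2, 3)
  expect_equal(accumulate(s)$cumulative_co2, c(1, 3, 6))
  # property: last cumulative equals the sum of dailies
  for (i in 1:10) {
    daily <- runif(sample(3:20, 1), 0, 50)
    expect_equal(max(make_series(daily)$cumulative_co2), sum(daily))
  }
})

test_that("control-vs-control subtraction is identically zero", {
  set.seed(11)
  for (i in 1:5) {
    ctl <- make_series(runif(10, 0, 30))
    expect_equal(subtract_baseline(ctl, ctl)$daily_co2, rep(0, 10))
  }
})

test_that("average_daily_rate divides window mass by window length", {
  expect_equal(average_daily_rate(make_series(rep(10, 28))), 10)
  expect_equal(average_daily_rate(make_series(c(0, 44, 44))), 88 / 3)
  s <- make_series(c(10, 20, 30))
  expect_equal(average_daily_rate(s, from = 1, to = 3), 25)
  expect_error(average_daily_rate(s, from = 2, to = 2), "empty window")
  expect_error(average_daily_rate(s, from = 0, to = 99), "span")
})

test_that("align_series interpolates cumulative CO2, flags filled days", {
  s <- make_series(c(10, 20, 30), days = c(1, 3, 5))  # cum 10, 30, 60
  a <- align_series(s, 1:5)
  expect_equal(a$cumulative_co2, c(10, 20, 30, 45, 60))
  expect_equal(a$interpolated, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_error(align_series(s, 0:6), "span")
})

test_that("resp_from_titration builds an ordered series", {
  rec <- data.frame(day = c(2, 1, 3), blank_volume_ml = 20,
                    sample_volume_ml = c(19, 19.5, 18), normality = 1)
  s <- resp_from_titration(rec)
  expect_equal(s$days, 1:3)
  expect_equal(s$daily_co2, c(0.5, 1, 2) * 22)
  rec$day <- c(1, 1, 2)
  expect_error(resp_from_titration(rec), "duplicate")
})

test_that("average_series pools replicates day by day", {
  avg <- average_series(list(make_series(c(2, 4)), make_series(c(4, 8))))
  expect_equal(avg$daily_co2, c(3, 6))
  expect_error(average_series(list(make_series(c(1, 2)),
                                   make_series(c(1, 2), days = c(2, 3)))),
               "common day grid")
})

test_that("nitrogen amendment arithmetic: 30 mg/mL x 10 mL over 1 kg", {
  expect_equal(nitrogen_amendment(30, 10, 1), 300)
})
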