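# Stoichiometry, substrate reconstruction and piecewise first-order fits.

test_that("CO2 <-> CH2 stoichiometry (44 mg CO2 per 14 mg CH2)", {
  expect_equal(co2_to_mineralized(0), 0)
  expect_equal(co2_to_mineralized(44), 14)
  expect_equal(co2_to_mineralized(2940), 935.4545, tolerance = 1e-6)
  expect_error(co2_to_mineralized(-1), "non-negative")
  # inverse scaling is the identity
  x <- runif(20, 0, 5000)
  expect_equal(mineralized_to_co2(co2_to_mineralized(x)), x)
})

test_that("fuel carbon content under the CH2 assumption", {
  expect_equal(fuel_carbon(0), 0)
  expect_equal(fuel_carbon(14), 12)
  expect_equal(round(fuel_carbon(2000), -2), 1700)
})

test_that("build_substrate_series inverts cumulative CO2", {
  resp <- make_series(c(44, 44), baseline_subtracted = TRUE)
  s <- build_substrate_series(resp, c0 = 2000, include_t0 = FALSE)
  expect_equal(s$c_t, c(1986, 1972))
  s0 <- build_substrate_series(resp, c0 = 2000)
  expect_equal(s0$days, c(0, 1, 2))
  expect_equal(s0$c_t, c(2000, 1986, 1972))
  # zero respiration: constant at c0
  z <- build_substrate_series(make_series(c(0, 0, 0),
                                          baseline_subtracted = TRUE), 500)
  expect_equal(z$c_t, rep(500, 4))
})

test_that("stoichiometric overdraw and missing baseline are errors", {
  resp <- make_series(c(2 * 100 * 44 / 14), baseline_subtracted = TRUE)
  expect_error(build_substrate_series(resp, c0 = 100), "overdraw")
  raw <- make_series(c(1, 2))
  expect_error(build_substrate_series(raw, 100), "baseline")
  expect_silent(build_substrate_series(raw, 100, require_baseline = FALSE))
})

test_that("fit_single_phase recovers a noiseless exponential exactly", {
  t <- 0:28
  s <- make_substrate(t, 1000 * exp(-0.02 * t), c0 = 1000)
  f <- fit_single_phase(s)
  expect_equal(f$k, 0.02, tolerance = 1e-10)
  expect_equal(f$rmse, 0, tolerance = 1e-12)
  expect_equal(f$c_start, 1000, tolerance = 1e-6)

  # constant series: k = 0, rmse = 0
  flat <- make_substrate(0:10, rep(750, 11), c0 = 750)
  f <- fit_single_phase(flat)
  expect_equal(f$k, 0)
  expect_equal(f$rmse, 0)

  # agreement with closed-form log-linear regression on noisy data
  set.seed(42)
  c_t <- 1000 * exp(-0.0258 * t) * exp(rnorm(29, 0, 0.03))
  s <- make_substrate(t, c_t, c0 = 1100)
  f <- fit_single_phase(s)
  ols <- stats::lm(log(c_t) ~ t)
  expect_equal(f$k, -unname(coef(ols)[2]), tolerance = 1e-10)
  # and the noiseless version is recovered to >= 4 significant figures
  f0 <- fit_single_phase(make_substrate(t, 1000 * exp(-0.0258 * t), 1000))
  expect_equal(f0$k, 0.0258, tolerance = 1e-6)
})

test_that("fit_single_phase validates its window", {
  s <- make_substrate(0:10, 1000 * exp(-0.05 * (0:10)), 1000)
  expect_error(fit_single_phase(s, t_start = 0, t_end = 1), "at least 3")
  # negative apparent slope clamps to zero with a warning
  up <- make_substrate(0:5, c(100, 110, 120, 130, 140, 150), 160)
  expect_warning(f <- fit_single_phase(up), "clamped")
  expect_equal(f$k, 0)
})

test_that("fixed-intercept and linear-objective fits behave", {
  t <- 0:20
  s <- make_substrate(t, 900 * exp(-0.03 * t), 900)
  f <- fit_single_phase(s, c_start = 900)
  expect_equal(f$k, 0.03, tolerance = 1e-10)
  fl <- fit_single_phase(s, objective = "linear")
  expect_equal(fl$k, 0.03, tolerance = 1e-6)
  expect_equal(fl$rmse, 0, tolerance = 1e-4)
})

test_that("fit_piecewise finds a noiseless two-phase breakpoint exactly", {
  tr <- make_decay(2000, 0, list(c(6, 0.05), c(Inf, 0.005)), 28)
  s <- make_substrate(tr$days, tr$c_t, 2000)
  f <- fit_piecewise(s, n_phases = 2)
  expect_equal(f$breakpoints, 6)
  expect_equal(f$phases$k, c(0.05, 0.005), tolerance = 1e-8)
  expect_equal(f$rmse, 0, tolerance = 1e-10)
  # single-phase fit on single-exponential data
  tr1 <- make_decay(1500, 0, list(c(Inf, 0.0162)), 28)
  f1 <- fit_piecewise(make_substrate(tr1$days, tr1$c_t, 1500), 1)
  expect_equal(f1$phases$k, 0.0162, tolerance = 1e-10)
})

test_that("phases are contiguous, cover the span, and RMSE nests", {
  set.seed(99)
  for (i in 1:10) {
    s <- random_substrate(sample(12:30, 1))
    f1 <- fit_piecewise(s, 1)
    f2 <- fit_piecewise(s, 2)
    f3 <- fit_piecewise(s, 3)
    # nested models: total RMSE non-increasing in n_phases
    expect_lte(f2$rmse, f1$rmse + 1e-12)
    expect_lte(f3$rmse, f2$rmse + 1e-12)
    for (f in list(f1, f2, f3)) {
      expect_equal(f$phases$t_start[1], min(s$days))
      expect_equal(f$phases$t_end[f$n_phases], max(s$days))
      if (f$n_phases > 1) {
        expect_equal(f$phases$t_start[-1],
                     f$phases$t_end[-f$n_phases])
      }
      expect_true(all(f$phases$k >= 0))
    }
  }
})

test_that("fit_piecewise equals the brute-force enumeration oracle", {
  set.seed(123)
  for (i in 1:15) {
    n <- sample(9:30, 1)
    s <- random_substrate(n)
    np <- sample(1:min(3, n %/% 3), 1)
    f <- suppressWarnings(fit_piecewise(s, np))
    o <- oracle_piecewise(s$days, s$c_t, np)
    expect_equal(f$rmse, o$rmse, tolerance = 1e-9)
    expect_equal(f$breakpoints, o$breakpoints)
    expect_equal(f$phases$k, o$ks, tolerance = 1e-8)
  }
})

test_that("series too short for the requested phases is an error", {
  s <- make_substrate(0:7, 1000 * exp(-0.01 * (0:7)), 1000)
  expect_error(fit_piecewise(s, 3), "at least 9")
})

test_that("summarize_k averages replicates per fuel", {
  out <- summarize_k(c(0.02, 0.03, 0.01), c("B100", "B100", "DIESEL"))
  expect_equal(out$mean_k[out$fuel == "B100"], 0.025)
  expect_equal(out$se_k[out$fuel == "B100"], sd(c(0.02, 0.03)) / sqrt(2))
  expect_false(out$se_defined[out$fuel == "DIESEL"])
  expect_true(is.na(out$se_k[out$fuel == "DIESEL"]))
  expect_error(summarize_k(numeric(0), character(0)), "no rate constants")
})
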