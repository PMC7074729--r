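# Synthetic microcosm generator: determinism, round-trips, booked truth.

test_that("same seed gives identical cohorts, different seeds differ", {
  cfg <- generator_config(replicates = 2, seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$titration, b$titration)
  expect_identical(a$endpoint, b$endpoint)
  c <- simulate_cohort(generator_config(replicates = 2, seed = 6))
  expect_false(identical(a$titration$sample_volume_ml,
                         c$titration$sample_volume_ml))
})

test_that("noiseless single-phase microcosm round-trips through the fits", {
  cfg <- generator_config(noise_sd_frac = 0, seed = 1)
  prof <- fuel_profile("B100", k = 0.031, lag_days = 0, n_use_pct = 10)
  sim <- simulate_microcosm(prof, cfg)
  ctl <- simulate_microcosm(NULL, cfg)
  net <- subtract_baseline(resp_from_titration(sim$titration, sim$spec),
                           resp_from_titration(ctl$titration, ctl$spec))
  s <- build_substrate_series(net, cfg$fuel_mass)
  f <- fit_single_phase(s)
  expect_equal(f$k, 0.031, tolerance = 1e-9)
  expect_equal(f$rmse, 0, tolerance = 1e-9)
})

test_that("booked fractions always sum to 100%", {
  coh <- simulate_cohort(generator_config(replicates = 2, seed = 3))
  for (tr in coh$truth) {
    if (is.null(tr$fractions)) next  # controls book nothing
    expect_equal(sum(tr$fractions), 100, tolerance = 1e-9)
    expect_true(all(tr$fractions >= 0))
  }
})

test_that("multi-phase profiles generate the booked k schedule", {
  cfg <- generator_config(noise_sd_frac = 0, seed = 2)
  prof <- fuel_profile("SYNTROLEUM",
                       phases = data.frame(duration = c(6, Inf),
                                           k = c(0.05, 0.008)),
                       lag_days = 3, n_use_pct = 20)
  sim <- simulate_microcosm(prof, cfg)
  expect_equal(sim$truth$phases$k, c(0, 0.05, 0.008))
  expect_equal(sim$truth$phases$t_end, c(3, 9, 28))
  ctl <- simulate_microcosm(NULL, cfg)
  net <- subtract_baseline(resp_from_titration(sim$titration, sim$spec),
                           resp_from_titration(ctl$titration, ctl$spec))
  f <- fit_piecewise(build_substrate_series(net, cfg$fuel_mass), 3)
  expect_equal(f$phases$k, c(0, 0.05, 0.008), tolerance = 1e-8)
  expect_equal(f$breakpoints, c(3, 9))
})

test_that("replicates = 0 yields controls only", {
  coh <- simulate_cohort(generator_config(replicates = 0, seed = 1))
  expect_identical(unique(coh$metadata$fuel), "CONTROL")
})

test_that("cohort CSVs round-trip through the readers without loss", {
  coh <- simulate_cohort(generator_config(replicates = 2, seed = 9))
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  titr <- read_titration_csv(file.path(dir, "titration.csv"))
  meta <- read_metadata_csv(file.path(dir, "metadata.csv"))
  endp <- read_endpoint_csv(file.path(dir, "endpoint.csv"))
  expect_equal(titr$sample_volume_ml, coh$titration$sample_volume_ml,
               tolerance = 1e-12)
  expect_identical(meta$microcosm_id, coh$metadata$microcosm_id)
  expect_equal(endp$n_final_mg, coh$endpoint$n_final_mg,
               tolerance = 1e-12)
})

test_that("grid mode steps daily CO2 by the configured multiplier", {
  cfg <- generator_config(noise_sd_frac = 0, grid_mode = TRUE,
                          replicates = 1, seed = 4)
  coh <- simulate_cohort(cfg)
  titr <- coh$titration
  ids <- c("B100_GRID_WITH_SOIL_r1", "CONTROL_GRID_WITH_SOIL_r1")
  s <- resp_from_titration(titr[titr$microcosm_id == ids[1], ])
  ctl <- resp_from_titration(titr[titr$microcosm_id == ids[2], ])
  net <- subtract_baseline(s, ctl)
  pre <- net$daily_co2[net$days == cfg$water_addition_day]
  post <- net$daily_co2[net$days == cfg$water_addition_day + 1]
  expect_equal(post / pre, 17)
  expect_equal(max(net$days), 41)
  # HTG multiplier ~5x
  htg <- subtract_baseline(
    resp_from_titration(titr[titr$microcosm_id == "HTG_GRID_WITH_SOIL_r1", ]),
    ctl)
  expect_equal(htg$daily_co2[htg$days == 29] /
                 htg$daily_co2[htg$days == 28], 5)
})

test_that("profile validation rejects impossible configurations", {
  expect_error(fuel_profile("B100", k = -0.1), ">= 0")
  expect_error(fuel_profile("CONTROL", k = 0.01))
  expect_error(fuel_profile("B100", k = 0.01, n_use_pct = 120), "\\[0, 100\\]")
  expect_error(generator_config(noise_sd_frac = -1), ">= 0")
  # booking over 100% of the fuel carbon is caught at simulate time
  cfg <- generator_config(noise_sd_frac = 0, seed = 1)
  greedy <- fuel_profile("B100", k = 0.05, n_use_pct = 100, lag_days = 0)
  expect_error(simulate_microcosm(greedy, cfg), "more than 100%")
})
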