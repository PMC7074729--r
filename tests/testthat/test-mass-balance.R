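# Nitrogen-based biomass, mineralized percent, DRO correction and the
# assembled carbon balance.

test_that("biomass_from_nitrogen implements the C5H7O2N stoichiometry", {
  expect_equal(biomass_from_nitrogen(0), 0)
  expect_equal(biomass_from_nitrogen(12, 300, 1700), 9.0756, tolerance = 1e-4)
  expect_equal(biomass_from_nitrogen(38.4, 300, 1700), 29.042,
               tolerance = 1e-4)
  expect_error(biomass_from_nitrogen(101), "\\[0, 100\\]")
  expect_error(biomass_from_nitrogen(10, 300, 0), "positive")
})

test_that("biomass_from_nitrogen is linear in %N and N0, inverse in C0", {
  p <- runif(10, 0, 40)
  expect_equal(biomass_from_nitrogen(2 * p, 300, 3400),
               biomass_from_nitrogen(p, 300, 1700))
  expect_equal(biomass_from_nitrogen(p, 600, 1700),
               2 * biomass_from_nitrogen(p, 300, 1700))
})

test_that("pct_mineralized converts CO2 carbon against initial carbon", {
  expect_equal(pct_mineralized(0, 1700), 0)
  expect_equal(pct_mineralized(44, 120), 10)
  expect_equal(pct_mineralized(1700 * 44 / 12, 1700), 100)
  expect_error(pct_mineralized(2 * 1700 * 44 / 12, 1700), "overdraw")
  # carbon and CH2 bases agree under the CH2 composition assumption
  co2 <- runif(10, 0, 4000)
  expect_equal(pct_mineralized(co2, 1714.2857, basis = "carbon"),
               pct_mineralized(co2, 1714.2857, basis = "ch2"))
})

test_that("correct_dro divides by surrogate recovery and flags outliers", {
  expect_equal(correct_dro(100, 1), 100)
  expect_equal(correct_dro(80, 0.8), 100)
  expect_error(correct_dro(80, 0), "> 0")
  expect_warning(correct_dro(80, 0.3), "suspect")
  d <- dro_result(80, 0.8, spiked_mass = 200)
  expect_equal(d$corrected_mass, 100)
  expect_equal(d$pct_remaining, 50)
  expect_false(d$recovery_flag)
  expect_true(suppressWarnings(dro_result(80, 1.6))$recovery_flag)
})

test_that("nitrogen_budget computes percent depletion", {
  nb <- nitrogen_budget(264, 300)
  expect_equal(nb$pct_used, 12)
  expect_error(nitrogen_budget(301, 300), "\\[0, n_initial\\]")
})

test_that("assemble_balance closes to exactly 100%", {
  spec <- microcosm_spec("d1", "DIESEL", 2000, 1000)
  c0 <- fuel_carbon(2000)
  # unreacted microcosm: everything residual
  resp <- make_series(c(0, 0, 0), baseline_subtracted = TRUE)
  bal <- assemble_balance(resp, dro_result(2000, 1),
                          nitrogen_budget(300, 300), spec,
                          volat_assumed_pct = 0)
  expect_equal(bal$pct_residual_dro, 100)
  expect_equal(bal$pct_mineralized, 0)
  expect_equal(bal$pct_biomass, 0)
  expect_equal(bal$pct_unaccounted, 0)

  # arithmetic closure: mineralized 34, residual 45, biomass 16, volat 0
  resp <- make_series(0.34 * c0 * 44 / 12, days = 1,
                      baseline_subtracted = TRUE)
  n_used_pct <- 16 * c0 / (300 * 60 / 14)
  bal <- assemble_balance(
    resp, dro_result(0.45 * c0 * 14 / 12, 1),
    nitrogen_budget(300 * (1 - n_used_pct / 100), 300), spec,
    volat_assumed_pct = 0)
  expect_equal(bal$pct_mineralized, 34)
  expect_equal(bal$pct_residual_dro, 45)
  expect_equal(bal$pct_biomass, 16)
  expect_equal(bal$pct_unaccounted, 5)
  total <- bal$pct_mineralized + bal$pct_residual_dro + bal$pct_biomass +
    bal$pct_volatilized + bal$pct_unaccounted
  expect_equal(total, 100, tolerance = 1e-9)
})

test_that("biomass is capped at the unallocated remainder", {
  spec <- microcosm_spec("d1", "DIESEL", 2000, 1000)
  c0 <- fuel_carbon(2000)
  resp <- make_series(0.70 * c0 * 44 / 12, days = 1,
                      baseline_subtracted = TRUE)
  # nitrogen implies 29% biomass but only 10% is unallocated
  expect_message(
    bal <- assemble_balance(resp, dro_result(0, 1),
                            nitrogen_budget(300 * (1 - 0.384), 300),
                            spec, volat_assumed_pct = 20),
    "capped")
  expect_equal(bal$pct_biomass, 10, tolerance = 1e-9)
  expect_true(bal$biomass_capped)
  expect_equal(bal$pct_unaccounted, 0, tolerance = 1e-9)
})

test_that("over-recovery yields a negative unaccounted with a warning", {
  spec <- microcosm_spec("d1", "DIESEL", 2000, 1000)
  c0 <- fuel_carbon(2000)
  resp <- make_series(0.50 * c0 * 44 / 12, days = 1,
                      baseline_subtracted = TRUE)
  expect_warning(
    bal <- assemble_balance(resp, dro_result(2000 * 0.6, 1),
                            nitrogen_budget(300, 300), spec,
                            volat_assumed_pct = 20),
    "over-recovery")
  expect_lt(bal$pct_unaccounted, 0)
  total <- bal$pct_mineralized + bal$pct_residual_dro + bal$pct_biomass +
    bal$pct_volatilized + bal$pct_unaccounted
  expect_equal(total, 100, tolerance = 1e-9)
})

test_that("a single component above 100% is an error naming it", {
  spec <- microcosm_spec("d1", "DIESEL", 2000, 1000)
  resp <- make_series(0, days = 1, baseline_subtracted = TRUE)
  expect_error(
    assemble_balance(resp, dro_result(3000, 1), nitrogen_budget(300, 300),
                     spec, volat_assumed_pct = 0),
    "pct_residual_dro")
})

test_that("per-fuel volatilization defaults follow the blend rule", {
  expect_equal(volatilization_default("DIESEL"), 20)
  expect_equal(volatilization_default("HTG"), 20)
  expect_equal(volatilization_default("SYNTROLEUM"), 20)
  expect_equal(volatilization_default("B20"), 4)
  expect_equal(volatilization_default("B100"), 0)
})
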