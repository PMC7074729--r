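# mineralize

Analysis of aerobic hydrocarbon-fuel biodegradation experiments measured by
alkaline-trap respirometry, for environmental microbiologists running soil
microcosm (or soil-free "fungi on a grid") incubations.

In these experiments a fuel (diesel, heating diesel, Fischer-Tropsch
synthetic diesel, fish biodiesel B100, or a B20 blend) is applied to a soil
bed in a sealed jar; evolved CO2 is captured in NaOH and quantified by
BaCl2 precipitation and back-titration. `mineralize` turns those raw
titration records into biological conclusions:

1. **Respirometry** — mg CO2 = (B − V) × N × 22 per trap reading
   (blank titrant volume B, sample volume V, normality N); daily and
   cumulative series, with uncontaminated-control baselines subtracted.
2. **Kinetics** — mineralization stoichiometry
   (2 CH₂ + 3 O₂ → 2 CO₂ + 2 H₂O, 44 mg CO2 per 14 mg CH2) reconstructs the
   remaining substrate C_t, fitted by the integral method
   ln C_t = ln C₀ − k t. Because fresh spills show an early fast phase and
   a late slow phase, separate rate constants can be fitted over 2–3
   contiguous phases; breakpoints are found by exhaustive search over the
   observed sampling days minimising log-space RMSE, with substrate mass
   continuous across breakpoints.
3. **Carbon mass balance** — initial fuel carbon (12/14 of the dose)
   partitioned into mineralized CO2-C (12/44), surrogate-recovery-corrected
   residual diesel-range organics (DRO), microbial biomass estimated from
   nitrogen depletion via the C₅H₇O₂N stoichiometry
   (60 mg biomass C per 14 mg N assimilated), an assumed volatilization
   allowance (≤ 20%), and an unaccounted remainder closing to 100%.
4. **Treatment statistics** — paired two-tailed t-tests, one-way ANOVA with
   Tukey HSD post hoc (applied only when the omnibus test is significant),
   standard errors.
5. **Synthetic data** — a fully seeded generator that emulates both the
   soil-bed experiment (28 days, lag then first-order decay, ~4.6%
   titration noise) and the suspended-grid volatiles experiment (41 days,
   low respiration stepping up 17× for B100 / ~5× for heating diesel after
   water addition at day 28), booking the true generating parameters for
   round-trip validation.

## Worked example

```r
library(mineralize)

cfg    <- generator_config(replicates = 3, seed = 42)  # 5 fuels + control
cohort <- simulate_cohort(cfg)
report <- analyze(cohort$metadata, cohort$titration, cohort$endpoint)
print(report)
```

```
<analysis_report>
  Whole-window first-order rate constants (per day):
       fuel n      mean_k         se_k se_defined
       B100 3 0.025377145 2.342963e-04       TRUE
        B20 3 0.016229045 4.206818e-05       TRUE
     DIESEL 3 0.010293999 7.220212e-05       TRUE
        HTG 3 0.008108767 4.091630e-05       TRUE
 SYNTROLEUM 3 0.015883127 6.218856e-05       TRUE
  Carbon balance (per-fuel means, % of initial C):
       fuel n mean_pct_mineralized mean_pct_residual_dro mean_pct_biomass
       B100 3                 49.0                  35.1            15.71
        B20 3                 35.0                  44.9            15.94
     DIESEL 3                 23.9                  47.1             8.91
        HTG 3                 19.4                  51.4             9.00
 SYNTROLEUM 3                 34.4                  16.8            28.71
 ...
  ANOVA on treatment groups: F = 3327.169, p = 1.43e-15
```

Biodiesel (B100) degrades fastest (k ≈ 0.025/d, ~49% of its carbon
mineralized in 28 days) while the petroleum diesels are slowest
(k ≈ 0.008–0.010/d, ~19–24% mineralized) — the ANOVA confirms the fuels
differ far beyond replicate noise. A piecewise fit resolves the lag phase
explicitly:

```r
fit_piecewise(report$kinetics[["B100_SOIL_BED_r1"]]$substrate, n_phases = 2)
#> <piecewise_fit> 2 phase(s), log-space RMSE 0.001869
#>  phase t_start t_end            k  c_start n_points
#>      1       0     2 1.764358e-05 2000.012        3
#>      2       2    28 2.628331e-02 1999.941       26
```

i.e. a ~2-day lag (k ≈ 0) followed by first-order decay at k ≈ 0.026/d.

## Command line

```sh
exec/mineralize simulate --out sim/ --seed 1
exec/mineralize analyze --metadata sim/metadata.csv \
    --titration sim/titration.csv --endpoint sim/endpoint.csv --out report/
exec/mineralize fit --metadata sim/metadata.csv \
    --titration sim/titration.csv --out fits/
```

Configuration overrides are JSON files passed via `--config` (keys mirror
`generator_config()` / `pipeline_options()` arguments).

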