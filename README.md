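# mehgrisk

Country-resolved assessment of dietary **methylmercury (MeHg) exposure** and
its health and economic consequences, for environmental-health modellers and
mercury-policy analysts.

Human MeHg exposure comes almost entirely from food — marine seafood,
freshwater fish, and rice. `mehgrisk` implements the full assessment chain:

1. **Exposure** — per-capita daily exposure
   `E = Σᵢ I·C (FW fish) + Σᵢ I·C (seafood) + I·C (rice)`, with intakes `I`
   (g/person/day) and geometric-mean concentrations `C` (µg/g) resolved over
   four trophic-level bins (2–2.5, 2.5–3.5, 3.5–4.5, 4.5–5), with a GLOBAL
   fallback for countries without concentration data and geometric
   farm/wild mixing.
2. **Future exposure** — proportional scaling of the 2010 concentrations by
   environmental proxies per emission scenario:
   `C_y^fw = C_2010^fw · D_y/D_2010` (country atmospheric deposition),
   `C_y^rice = C_2010^rice · S_y/S_2010` (country soil Hg),
   `C_y^sea = C_2010^sea · P_y/P_2010` (global plankton MeHg). Five built-in
   scenarios: CP, NP-Delayed, MFR, A1B, A2.
3. **Health endpoints** — linear fetal IQ decrement
   `ΔIQ = γλβ · intake` (γ = 0.3, λ = 0.2, β = 0.6) and log-linear fatal
   heart attacks `ΔCF = Σ_g POP_g · Cf_g · ω · (1 − e^{−φλβ·intake})`
   (φ = 0.066, ω = 0.33), plus blood/hair biomarkers for evaluation.
4. **Valuation** — $18,832 per IQ point and a $6.3M value of statistical
   life, transferred by PPP-GDP ratio to the US, with 3% discounting of
   2010–2050 losses to the 2050 horizon.
5. **Uncertainty** — 1000-draw Monte Carlo over four factor groups
   (consumption, concentrations, dose-response, valuation) with 2.5/97.5
   percentile intervals and one-factor-at-a-time envelopes.
6. **Synthetic worlds** — a calibrated generator
   (`generate_world()`) emulating the statistical structure of the real
   food-balance / concentration / demographic / economic databases, so the
   entire pipeline runs and is testable offline.

See `vignettes/mehgrisk-methods.Rmd` for the model, its assumptions, the
calibration of every default, and known limitations.

## Worked example

```r
library(mehgrisk)

# closed-form spot checks: IQ decrement and blood Hg at record-level diets
per_fetus_iq(33)      # 1.188 IQ points per fetus at 33 ug/day
biomarkers(16)$blood  # 9.6 ug/L blood at 16 ug/day

# a 30-country synthetic world and the present-day baseline
world <- generate_world(synthetic_world_config(n_countries = 30, seed = 42))
base  <- run_baseline(world)
attr(base, "global")
#> $total_iq     12519300      # IQ points lost per year, all countries
#> $per_fetus_iq 0.0866        # points per newborn (world mean)
#> $fha_deaths   35081         # attributable fatal heart attacks per year
#> $total_usd    1.15e+11      # annual loss, USD

# scenario projection to 2050 and cumulative discounted losses
sc <- run_scenarios(world)
sc$cumulative
#>   scenario   cumulative_usd
#>   A1B              1.17e13
#>   A2               1.10e13
#>   CP               9.76e12
#>   MFR              8.71e12
#>   NP-Delayed       9.15e12

# Monte Carlo uncertainty for the CP cumulative loss
run_uncertainty(world, uncertainty_spec(n_draws = 1000, seed = 1))
#> Monte Carlo cumulative_loss (CP, 1000 draws):
#>   point 9.764e+12, 95% CI [1.462e+12, 1.779e+13]
#>   one-factor-at-a-time envelopes:
#>     consumption    [8.978e+12, 1.086e+13]
#>     concentration  [8.199e+12, 1.242e+13]
#>     dose_response  [2.766e+12, 2.164e+13]
#>     valuation      [2.929e+12, 1.19e+13]
```

The baseline table ranks countries by total loss; high-seafood island
countries top the per-fetus IQ ranking while populous mid-exposure
countries dominate deaths and monetary losses. In the uncertainty report
the dose-response envelope is the widest of the four factor groups.

A thin command-line wrapper around the same functions is installed at
`inst/scripts/mehg-pipeline.R` (subcommands `generate-world`,
`run-baseline`, `run-scenarios`, `run-uncertainty`).

## Acceptance script

`scripts/acceptance.R` recomputes the desk-scale reference quantities by
running the installed package end to end — encoding the printed per-capita
dietary intakes of three high-seafood reference populations as
intake/concentration tables, aggregating exposure, and applying the
dose-response chain — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
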