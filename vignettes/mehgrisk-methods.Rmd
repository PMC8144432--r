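---
title: "Methods: dietary methylmercury exposure, health effects, and valuation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary methylmercury exposure, health effects, and valuation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mehgrisk)
```

## The problem

Methylmercury (MeHg) is a bioaccumulating neurotoxin that reaches people
almost entirely through diet: marine seafood, freshwater fish and other
aquatic animals, and — in parts of Asia — rice grown on soils that receive
atmospheric mercury deposition. Prenatal exposure lowers the IQ of newborns;
chronic adult exposure is associated with fatal heart attacks (FHA). Because
future anthropogenic mercury emissions may range from aggressive reduction
to strong growth, a country-resolved model that links emissions-driven
environmental change to dietary exposure, health endpoints, and monetised
damages is the natural policy-evaluation tool. `mehgrisk` implements that
chain as a small, fully testable R package.

## Exposure model

Per-capita daily exposure for a country is

$$E \;=\; \sum_{i=1}^{4} I^{\mathrm{fw}}_i C^{\mathrm{fw}}_i
      \;+\; \sum_{i=1}^{4} I^{\mathrm{sea}}_i C^{\mathrm{sea}}_i
      \;+\; I^{\mathrm{rice}} C^{\mathrm{rice}},$$

where $I$ is intake (g/person/day) and $C$ a geometric-mean MeHg
concentration (µg/g), summed over four trophic-level bins
(2–2.5, 2.5–3.5, 3.5–4.5, 4.5–5). Concentrations rise roughly tenfold from
the lowest to the highest bin, which is why binning matters more than
species identity. Key conventions:

* **Units.** Intakes are carried internally in g/person/day;
  `kg_per_year_to_g_per_day()` converts food-balance-style annual figures
  (`× 1000 / 365.25`).
* **Binning.** Bins are left-closed (`[2, 2.5), [2.5, 3.5), …`), with the
  top bin closed so trophic level 5 is representable. Per-bin geometric
  means are used because concentration data are approximately log-normal.
* **Missing inventories.** When a country lacks a bin-resolved consumption
  inventory, `allocate_fish_consumption()` falls back on the marine trophic
  index (MTI). The fallback's functional form is not fixed by any source we
  know of; we assign all consumption to the single bin containing the MTI
  (our choice), with a triangular spread over adjacent bins available via
  `spread = "triangular"`.
* **Missing concentrations.** Countries without concentration data silently
  (with a logged message) fall back to the GLOBAL geometric-mean record;
  missing *intake* records are a hard error, since intake defines which
  countries exist.
* **Farm/wild.** Where concentration records distinguish farm-raised from
  wild-caught fish, they are combined as the farm-fraction-weighted
  geometric mixture $\exp(f \ln c_{\mathrm{farm}} + (1-f) \ln
  c_{\mathrm{wild}})$. A geometric mixture (our choice; the mixing rule is
  not specified by the sources) preserves geometric-mean semantics and makes
  the combination exact under log-normal assumptions.

## Future exposure

Food consumption patterns are held constant; concentrations are scaled by
environmental proxies simulated (in the original work) by a coupled
atmosphere–land–ocean–ecosystem model chain, which this package does not
reimplement (see Non-goals):

$$C^{\mathrm{fw}}_{y} = C^{\mathrm{fw}}_{2010}\,\frac{D_y}{D_{2010}},\qquad
  C^{\mathrm{rice}}_{y} = C^{\mathrm{rice}}_{2010}\,\frac{S_y}{S_{2010}},\qquad
  C^{\mathrm{sea}}_{y} = C^{\mathrm{sea}}_{2010}\,\frac{P_y}{P_{2010}},$$

with $D$ the country's atmospheric Hg deposition, $S$ its soil Hg
concentration, and $P$ the *global* harvest-weighted plankton MeHg
concentration (seafood markets are global; rivers and paddies are not).
`scale_concentrations()` applies these rules to a table;
`run_scenarios()` uses the equivalent pathway-ratio shortcut, which is
exact because the scaling is linear within each pathway.

Five emission scenarios are built in (`scenario_definitions()`), anchored at
a 2010 inventory of 1890 Mg/yr: CP (current policy, near-constant, with a
small rise to 1960 Mg/yr by 2035), NP-Delayed (reduction to 1020 Mg/yr by
2050), MFR (maximum feasible reduction, 300 Mg/yr), A1B (4900 Mg/yr) and A2
(3900 Mg/yr). Interpolation between anchors is linear in time — the
published trajectories are near-piecewise-linear and no functional form is
stated.

## Health endpoints

A one-compartment pharmacokinetic chain links intake to biomarkers:
blood Hg $C^{\mathrm{blood}} = \beta \cdot \mathrm{intake}$ (µg/L, with
$\beta = 0.6$ per µg/day) and hair Hg $C^{\mathrm{hair}} = \lambda
C^{\mathrm{blood}}$ (µg/g, $\lambda = 0.2$).

* **IQ decrement** (linear, no threshold): $\Delta IQ = \gamma \lambda
  \beta \cdot \mathrm{intake}$ per fetus, $\gamma = 0.3$ IQ points per µg/g
  hair; multiplied by annual births for the cohort total. The "estimated
  daily intake per body weight times body weight" product collapses to
  daily intake, so the (never separately used) body weight cancels out of
  every endpoint; `dose_response_params()` retains `bw` (60 kg) only for
  per-kg reporting.
* **Fatal heart attacks** (log-linear in hair Hg): per gender $g$,
  $\Delta CF = \sum_g POP_g\, Cf_g\, \omega\,(1 -
  e^{-\varphi \lambda \beta \cdot \mathrm{intake}})$ with $\varphi = 0.066$
  per µg/g and a probability-of-causality weight $\omega = 0.33$ reflecting
  the limited epidemiological base. The response is zero at zero intake and
  saturates at $\omega$ times baseline FHA deaths. A single national intake
  is applied to both genders (no gendered consumption data exist at this
  resolution).

## Economic valuation

IQ points are valued at \$18,832 each (2008 USD; low alternative \$8,013),
deaths at a \$6.3 million value of statistical life (2005 USD; plausible
range \$1–10 million). Both are US values transferred to other countries by
the ratio of PPP-adjusted per-capita GDP to the US value, with unit income
elasticity. Two documented placeholders/choices:

* The deflators converting 2008/2005 USD to the 2020 reporting year default
  to 1.0 because the source inflation series is unstated; they are plain
  config values (`deflator_2008`, `deflator_2005`).
* "Realised to 2050 at 3%" is implemented as *forward compounding* of each
  year's loss to the 2050 horizon ($\sum_y L_y (1+r)^{2050-y}$), matching
  the future-value phrasing; a present-value-at-2010 convention is
  selectable. IQ earnings losses are taken as a lump value in the birth
  year, not as discounted lifetime streams.

## Uncertainty propagation

`run_monte_carlo()` repeats the full pipeline (default 1000 draws) with
four factor groups perturbed, and reports the 2.5th/97.5th percentiles of
the draws (type-7 quantiles, R's default linear interpolation between order
statistics — the percentile rule is otherwise unstated). Distribution
shapes are our calibration of stated ranges:

| group | distribution | calibration |
|---|---|---|
| consumption | log-normal multiplier, one per country | 95% range spans a factor of 2 (survey vs food-balance agreement) |
| concentration | log-normal multiplier per (category, bin) | table-supplied geometric SD (synthetic default 1.3, uncertainty of the *mean*) |
| dose-response | truncated normals at 0 for $\beta, \lambda$ (CV 0.15), $\gamma, \varphi$ (CV 0.5); two-point ±50% for $\omega$ | pharmacokinetics vary 10–20%; effect coefficients dominate overall uncertainty |
| valuation | two-point {8013, 18832} for the IQ value; log-uniform \$1–10M for the VSL | stated high/low values and range |

Sampling is at the factor-group level (one multiplier per country for
intake, one per category-bin for concentration), mirroring grouped
sensitivity bars; per-record sampling would be finer-grained than any
stated range. Because per-country multipliers are independent, the
consumption envelope of a many-country world is narrower relative to its
point value than a single-multiplier design would give — a known,
documented consequence of the grouped design. One draw evaluates the whole
2010–2050 pipeline via precomputed country × year matrices, so 1000 draws
take about a second. `factor_sensitivity()` reruns the Monte Carlo with one
group varying at a time; with the default calibration the dose-response
envelope is the widest of the four, and a degenerate spec (empty `vary`)
collapses every envelope onto the point estimate. Draws are a deterministic
function of (seed, spec, world); `sample_parameters()` reproduces the exact
bundle of any draw index.

## The synthetic world

`generate_world()` emulates the statistical structure of the real input
databases so the full pipeline and all tests run with no download. What it
states, once:

* **Archetypes.** Three country archetypes with mean intakes
  (seafood/freshwater-fish/rice, g/day): island-high-seafood (120/5/100),
  asian-rice-freshwater (45/40/250), inland-low (8/12/150); 10/40/50% of
  countries and 0.3/49/50.7% of a 7-billion world population. Archetype
  structure (rather than independent sampling) makes exposure rankings
  island > coastal > inland structurally guaranteed for tests.
* **Concentrations.** Bin geometric means follow $c_0 \cdot
  10^{(i-1)/3}$, an exact tenfold span across bins; $c_0$ = 0.0178
  (seafood), 0.0119 (freshwater fish) µg/g, rice 0.0016 µg/g. Wild-caught
  records are 1.15× and farm-raised 0.7× the bin mean, with a farm fraction
  of 0.3 (the geometric mixture then sits within ~1% of the bin mean).
  Per-country log-normal jitter: SD 0.15 (log scale), one multiplier per
  country-category so the within-country span stays exact.
* **Calibration targets.** These choices were solved — once, before any
  test was run — so that the default world lands near the printed global
  anchors of the assessment it emulates: population-weighted pathway shares
  ≈ 56/34/10%, mean exposure ≈ 2.4 µg/day giving ≈ 1.2 × 10⁷ IQ
  points/yr (≈ 0.086/fetus), FHA incidences (8.6/4.7 × 10⁻⁴ per yr,
  male/female) giving ≈ 29,000 deaths/yr, and a GDP distribution
  (log-normal, median \$15,500, log-SD 0.6, US \$63,000) giving ≈ \$115B/yr
  of losses. The first island country's seafood intake is solved exactly so
  its seafood exposure equals the 33 µg/day record value. Tests assert
  these only at order-of-magnitude tolerance; the world is synthetic, not a
  reconstruction of the real country tables.
* **Trajectories.** 2050 deposition responses per scenario (relative to the
  flat CP reference): MFR 0.52, NP-Delayed 0.72, A2 1.59, A1B 1.87; soil
  responses 0.97–1.04. The plankton response is the deposition response
  dampened by a factor 0.5 on its deviation from 1: the published realised
  health responses (−24% IQ under a −48% deposition change) imply
  substantial dampening that the source text does not quantify, so the
  factor is an explicit calibration parameter. Time paths are
  logistic-in-time between the 2010 and 2050 endpoints (smooth, monotone;
  the true shape is unstated). Demographics grow 0.7–1.2%/yr by archetype
  (≈ +45% world population by 2050), births are near-flat (+0.1%/yr), and
  per-capita GDP grows 2%/yr everywhere (middle-of-the-road).

What the generator does **not** emulate: species-level consumption,
spatially resolved (gridded) exposure, high-exposure subpopulations
(artisanal gold miners, marine-mammal consumers), correlations between
national income and diet, and interannual environmental variability. A
green test on the synthetic world therefore establishes that the *pipeline
arithmetic and its invariants* are right, not that any real country's
burden is.

## Numerical choices and degenerate inputs

* Geometric means are computed in log space; non-positive concentrations
  are rejected with the offending sample named.
* Anchor interpolation refuses extrapolation outside the anchor span.
* Proportional scaling guards against non-positive 2010 proxies.
* The FHA saturation bound is approached smoothly; intakes far above
  ~10³ µg/day saturate to the bound within double precision.
* Monte Carlo draws consume a fixed number of RNG calls regardless of which
  groups vary or how wide their dispersions are, so seeds remain comparable
  across specs (this is what makes "enlarging a dispersion never narrows
  the CI" hold draw-by-draw, and degenerate specs collapse exactly).

## Known limitations

The package deliberately stops at the reduced-form exposure scaling: it
cannot generate environmental trajectories from emissions mechanistically,
so scenario results are only as good as the supplied (or synthetically
calibrated) proxy responses. Nutritional offsets of fish consumption,
age-structured exposure, thresholded dose-response variants, and correlated
parameter sampling are out of scope.
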