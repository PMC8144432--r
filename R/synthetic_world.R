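# Synthetic input worlds.
#
# The generator stands in for the food-balance, concentration-literature,
# demographic, and socio-economic databases the full assessment draws on. It
# is calibrated once to the printed global anchors of the assessment it
# emulates -- a ~10x concentration span across trophic bins, global pathway
# shares of roughly 56/34/10 % (seafood / freshwater fish / rice), a world
# population of 7e9 with ~1.4e8 births/yr, ~0.7 per 1000 baseline
# fatal-heart-attack incidence, and 2050 environmental responses per
# emission scenario -- and is not tuned beyond that. Countries follow three
# dietary archetypes (island-high-seafood, asian-rice-freshwater,
# inland-low) with multiplicative jitter, so exposure rankings
# (island > coastal > inland) are structurally guaranteed.

#' Configuration for the synthetic-world generator
#'
#' Defaults encode the stated world; see the methods vignette for the
#' calibration rationale of every number.
#'
#' @param n_countries Number of countries to generate (default 30).
#' @param seed RNG seed; the world is a deterministic function of the
#'   configuration including the seed.
#' @param archetypes Tibble defining the dietary archetypes: columns
#'   `archetype`, `count_share` (fraction of countries), `pop_share`
#'   (fraction of world population), `seafood`, `freshwater_fish`, `rice`
#'   (mean intakes, g/person/day), `birth_rate` (births per person per
#'   year), `pop_growth` (annual population growth rate).
#' @param conc_base Named vector of base geometric-mean concentrations
#'   (ug/g): lowest-trophic-bin value for `seafood` and `freshwater_fish`,
#'   the single value for `rice`.
#' @param conc_span Ratio of highest to lowest trophic-bin geometric mean
#'   (default 10).
#' @param bin_fractions List with elements `seafood` and `freshwater_fish`:
#'   length-4 fractions allocating fish consumption across trophic bins.
#' @param wild_factor,farm_factor Multipliers on the bin mean for
#'   wild-caught and farm-raised fish (defaults 1.15, 0.7).
#' @param farm_fraction Fraction of fish consumption that is farm-raised
#'   (default 0.3).
#' @param mean_gsd Geometric standard deviation attached to every
#'   concentration record, representing uncertainty of the geometric mean
#'   (default 1.3).
#' @param intake_sdlog,conc_sdlog,pop_sdlog Log-scale SDs of the country
#'   jitter on intakes, concentrations, and population weights.
#' @param total_population World population in 2010 (default 7e9).
#' @param fha_incidence Named vector, baseline fatal-heart-attack incidence
#'   per person per year by gender.
#' @param gdp_median,gdp_sdlog Log-normal parameters of 2010 PPP per-capita
#'   GDP across countries (USD).
#' @param us_gdp US PPP per-capita GDP in 2010 (USD, default 63000).
#' @param gdp_growth Annual per-capita GDP growth rate, applied to all
#'   countries and the US (SSP2-like middle of the road, default 0.02).
#' @param births_growth Annual growth rate of births (default 0.001,
#'   near-flat cohorts).
#' @param years Years covered by the trajectories (default 2010:2050).
#' @param island_anchor_exposure If non-NULL, the first island country's
#'   seafood intake is calibrated so its seafood exposure equals this value
#'   in ug/day (default 33, the highest national value on record); NULL
#'   disables the anchor.
#' @param deposition_response Named vector: 2050 atmospheric-deposition
#'   ratio (relative to the flat CP reference) per scenario.
#' @param soil_response Named vector: 2050 soil-Hg ratio per scenario.
#' @param plankton_dampening Factor applied to the deviation-from-1 of the
#'   deposition response to obtain the plankton response (default 0.5).
#' @param logistic_rate,logistic_mid Shape parameters of the
#'   logistic-in-time interpolation between the 2010 and 2050 endpoints of
#'   each proxy trajectory.
#' @return A list of class `"mehg_world_config"`.
#' @export
synthetic_world_config <- function(
    n_countries = 30,
    seed = 42,
    archetypes = tibble::tribble(
      ~archetype, ~count_share, ~pop_share, ~seafood, ~freshwater_fish, ~rice, ~birth_rate, ~pop_growth,
      "island",           0.10,      0.003,      120,                5,   100,       0.018,       0.008,
      "asian",            0.40,      0.490,       45,               40,   250,       0.017,       0.007,
      "inland",           0.50,      0.507,        8,               12,   150,       0.024,       0.012
    ),
    conc_base = c(seafood = 0.0178, freshwater_fish = 0.0119, rice = 0.0016),
    conc_span = 10,
    bin_fractions = list(
      seafood = c(0.2, 0.5, 0.25, 0.05),
      freshwater_fish = c(0.3, 0.5, 0.2, 0)
    ),
    wild_factor = 1.15,
    farm_factor = 0.7,
    farm_fraction = 0.3,
    mean_gsd = 1.3,
    intake_sdlog = 0.2,
    conc_sdlog = 0.15,
    pop_sdlog = 0.5,
    total_population = 7e9,
    fha_incidence = c(male = 8.6e-4, female = 4.7e-4),
    gdp_median = 15500,
    gdp_sdlog = 0.6,
    us_gdp = 63000,
    gdp_growth = 0.02,
    births_growth = 0.001,
    years = 2010:2050,
    island_anchor_exposure = 33,
    deposition_response = c(CP = 1, `NP-Delayed` = 0.72, MFR = 0.52,
                            A2 = 1.59, A1B = 1.87),
    soil_response = c(CP = 1, `NP-Delayed` = 0.99, MFR = 0.97,
                      A2 = 1.02, A1B = 1.04),
    plankton_dampening = 0.5,
    logistic_rate = 0.15,
    logistic_mid = 2030) {
  if (n_countries < 1) abort("`n_countries` must be >= 1.")
  if (abs(sum(archetypes$count_share) - 1) > 1e-9) {
    abort("Archetype `count_share` values must sum to 1.")
  }
  if (abs(sum(archetypes$pop_share) - 1) > 1e-9) {
    abort("Archetype `pop_share` values must sum to 1.")
  }
  for (f in bin_fractions) {
    if (length(f) != 4 || any(f < 0) || abs(sum(f) - 1) > 1e-9) {
      abort("Each `bin_fractions` element must be 4 non-negative fractions summing to 1.")
    }
  }
  if (any(conc_base <= 0) || conc_span <= 0 || total_population <= 0) {
    abort("Concentration bases, span, and population must be > 0.")
  }
  if (!"CP" %in% names(deposition_response)) {
    abort("`deposition_response` must include the CP reference scenario.")
  }
  structure(as.list(environment()), class = "mehg_world_config")
}

# bin geometric means for a fish category: base * span^((0:3)/3)
bin_means <- function(base, span) base * span^((0:3) / 3)

# largest-remainder allocation of n countries to archetype counts, keeping
# every archetype with positive share represented when n allows
archetype_counts <- function(shares, n) {
  raw <- shares * n
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  if (n >= length(shares)) {
    while (any(counts == 0 & shares > 0)) {
      i <- which(counts == 0 & shares > 0)[1]
      j <- which.max(counts)
      counts[i] <- counts[i] + 1
      counts[j] <- counts[j] - 1
    }
  }
  counts
}

#' Generate a complete synthetic input world
#'
#' Produces all tables the pipeline consumes: food intake, concentrations
#' (with farm/wild origins and a GLOBAL fallback), farm fractions,
#' demographic and economic trajectories over the configured years, and the
#' per-scenario environmental proxy trajectories. Deterministic for a fixed
#' configuration (including the seed).
#'
#' @param config A [synthetic_world_config()].
#' @return A list of class `"mehg_world"` with elements `countries`,
#'   `intake`, `concentrations`, `farm_fractions`, `demographics`,
#'   `economics`, `trajectories`, and `config`.
#' @export
#' @examples
#' world <- generate_world(synthetic_world_config(n_countries = 5, seed = 1))
#' world$countries
generate_world <- function(config = synthetic_world_config()) {
  if (!inherits(config, "mehg_world_config")) {
    abort("`config` must come from synthetic_world_config().")
  }
  set.seed(config$seed)
  arch <- config$archetypes
  counts <- archetype_counts(arch$count_share, config$n_countries)
  prefix <- c(island = "SI", asian = "SA", inland = "SL")

  countries <- purrr::map_dfr(seq_len(nrow(arch)), function(i) {
    k <- counts[i]
    if (k == 0) return(NULL)
    w <- rlnorm(k, 0, config$pop_sdlog)
    tibble::tibble(
      country = sprintf("%s%02d", prefix[[arch$archetype[i]]], seq_len(k)),
      archetype = arch$archetype[i],
      population = config$total_population * arch$pop_share[i] * w / sum(w),
      birth_rate = arch$birth_rate[i] * rlnorm(k, 0, 0.1),
      pop_growth = arch$pop_growth[i],
      seafood_mean = arch$seafood[i],
      fw_mean = arch$freshwater_fish[i],
      rice_mean = arch$rice[i]
    )
  })

  bins <- trophic_bins()$bin

  # concentrations: one country-level multiplicative jitter per (country,
  # category) so the cross-bin span stays exact within each country
  conc_rows <- list()
  for (cat in .fish_categories) {
    means <- bin_means(config$conc_base[[cat]], config$conc_span)
    jit <- rlnorm(nrow(countries), 0, config$conc_sdlog)
    for (orig in c("wild", "farm")) {
      fac <- if (orig == "wild") config$wild_factor else config$farm_factor
      conc_rows[[length(conc_rows) + 1]] <- tibble::tibble(
        country = rep(countries$country, each = length(bins)),
        category = cat,
        bin = rep(bins, nrow(countries)),
        origin = orig,
        concentration = rep(jit, each = length(bins)) * rep(means, nrow(countries)) * fac,
        gsd = config$mean_gsd
      )
      conc_rows[[length(conc_rows) + 1]] <- tibble::tibble(
        country = "GLOBAL", category = cat, bin = bins, origin = orig,
        concentration = means * fac, gsd = config$mean_gsd
      )
    }
  }
  rice_jit <- rlnorm(nrow(countries), 0, config$conc_sdlog)
  conc_rows[[length(conc_rows) + 1]] <- tibble::tibble(
    country = c(countries$country, "GLOBAL"),
    category = "rice", bin = NA_character_, origin = "all",
    concentration = c(rice_jit, 1) * config$conc_base[["rice"]],
    gsd = config$mean_gsd
  )
  concentrations <- concentration_table(dplyr::bind_rows(conc_rows))

  farm_fractions <- tidyr::expand_grid(
    country = countries$country,
    category = .fish_categories
  ) |>
    dplyr::mutate(farm_fraction = config$farm_fraction)

  # intakes: archetype means with multiplicative jitter; fish split across
  # bins by the fixed default fractions
  intake_rows <- purrr::pmap(
    list(countries$country, countries$seafood_mean, countries$fw_mean,
         countries$rice_mean),
    function(ctry, sf, fw, rice) {
      totals <- c(seafood = sf, freshwater_fish = fw, rice = rice) *
        rlnorm(3, 0, config$intake_sdlog)
      fish <- purrr::map_dfr(.fish_categories, function(cat) {
        tibble::tibble(
          country = ctry, category = cat, bin = bins,
          intake = totals[[cat]] * config$bin_fractions[[cat]]
        )
      })
      dplyr::bind_rows(fish, tibble::tibble(
        country = ctry, category = "rice", bin = NA_character_,
        intake = totals[["rice"]]
      ))
    }
  )
  intake <- intake_table(dplyr::bind_rows(intake_rows))

  # anchor the first island country's seafood exposure to the configured
  # record value by solving for its total seafood intake
  if (!is.null(config$island_anchor_exposure) && any(countries$archetype == "island")) {
    anchor <- countries$country[countries$archetype == "island"][1]
    frac <- config$bin_fractions$seafood
    eff <- sum(vapply(seq_along(bins), function(i) {
      r <- resolve_concentration(concentrations, anchor, "seafood", bins[i],
                                 config$farm_fraction, quiet = TRUE)
      frac[i] * r$concentration
    }, numeric(1)))
    sel <- intake$country == anchor & intake$category == "seafood"
    intake$intake[sel] <- frac * config$island_anchor_exposure / eff
  }

  years <- config$years
  cf_jit_m <- rlnorm(nrow(countries), 0, 0.15)
  cf_jit_f <- rlnorm(nrow(countries), 0, 0.15)
  demographics <- purrr::map_dfr(seq_len(nrow(countries)), function(i) {
    ci <- countries[i, ]
    pop <- ci$population * (1 + ci$pop_growth)^(years - 2010)
    births <- ci$birth_rate * ci$population * (1 + config$births_growth)^(years - 2010)
    dplyr::bind_rows(
      tibble::tibble(country = ci$country, year = years, gender = "male",
                     population = pop / 2,
                     fha_incidence = config$fha_incidence[["male"]] * cf_jit_m[i],
                     births = births),
      tibble::tibble(country = ci$country, year = years, gender = "female",
                     population = pop / 2,
                     fha_incidence = config$fha_incidence[["female"]] * cf_jit_f[i],
                     births = births)
    )
  })
  demographics <- demographics_table(demographics)

  gdp0 <- rlnorm(nrow(countries), log(config$gdp_median), config$gdp_sdlog)
  economics <- purrr::map_dfr(seq_len(nrow(countries)), function(i) {
    tibble::tibble(
      country = countries$country[i],
      year = years,
      gdp_pc_ppp = gdp0[i] * (1 + config$gdp_growth)^(years - 2010),
      us_gdp_pc_ppp = config$us_gdp * (1 + config$gdp_growth)^(years - 2010)
    )
  })
  economics <- economics_table(economics)

  trajectories <- generate_scenario_trajectories(config)

  structure(
    list(
      countries = countries[, c("country", "archetype", "population")],
      intake = intake,
      concentrations = concentrations,
      farm_fractions = farm_fractions,
      demographics = demographics,
      economics = economics,
      trajectories = trajectories,
      config = config
    ),
    class = "mehg_world"
  )
}

#' @export
print.mehg_world <- function(x, ...) {
  cat(sprintf(
    "Synthetic MeHg exposure world: %d countries (%s), years %d-%d, seed %s\n",
    nrow(x$countries),
    paste(sprintf("%d %s", table(x$countries$archetype)[unique(x$countries$archetype)],
                  unique(x$countries$archetype)), collapse = ", "),
    min(x$config$years), max(x$config$years), format(x$config$seed)
  ))
  invisible(x)
}

#' Generate per-scenario environmental proxy trajectories
#'
#' Yearly global trajectories of the three proxies (atmospheric deposition
#' D, soil Hg S, plankton MeHg P), each normalised to 1 in 2010, following a
#' smooth logistic-in-time path to the configured 2050 response. The CP
#' scenario is the flat reference (all proxies identically 1); the plankton
#' response is the deposition response dampened by `plankton_dampening`.
#'
#' @param config A [synthetic_world_config()].
#' @return A validated trajectory table with `country = "GLOBAL"` rows for
#'   every scenario and year.
#' @export
generate_scenario_trajectories <- function(config = synthetic_world_config()) {
  if (!"CP" %in% names(config$deposition_response)) {
    abort("`deposition_response` must include the CP reference scenario.")
  }
  years <- config$years
  p <- stats::plogis(config$logistic_rate * (years - config$logistic_mid))
  p0 <- stats::plogis(config$logistic_rate * (2010 - config$logistic_mid))
  p1 <- stats::plogis(config$logistic_rate * (2050 - config$logistic_mid))
  s <- (p - p0) / (p1 - p0)
  out <- purrr::map_dfr(names(config$deposition_response), function(sc) {
    dep <- config$deposition_response[[sc]]
    soil <- config$soil_response[[sc]] %||% 1
    plank <- 1 + config$plankton_dampening * (dep - 1)
    tibble::tibble(
      scenario = sc, country = "GLOBAL", year = years,
      D = 1 + (dep - 1) * s,
      S = 1 + (soil - 1) * s,
      P = 1 + (plank - 1) * s
    )
  })
  trajectory_table(out)
}
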