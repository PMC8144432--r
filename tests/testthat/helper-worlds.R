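# Shared fixtures and independent oracles. The oracles deliberately use
# plain base-R loops (no package pipeline functions) so they can serve as
# independent recomputations of the same quantities.

# A small hand-constructed world with one country and clean round numbers.
tiny_world <- function(cf_male = 0.002, cf_female = 0.001, births = 1e5,
                       pop = 1e6, gdp = 31500, us_gdp = 63000) {
  intake <- intake_table(data.frame(
    country = "AAA",
    category = c("seafood", "freshwater_fish", "rice"),
    bin = c("3.5-4.5", "2.5-3.5", NA),
    intake = c(10, 5, 200)
  ))
  conc <- concentration_table(data.frame(
    country = "GLOBAL",
    category = c("seafood", "freshwater_fish", "rice"),
    bin = c("3.5-4.5", "2.5-3.5", NA),
    origin = "all",
    concentration = c(0.1, 0.2, 0.005)
  ))
  demo <- demographics_table(data.frame(
    country = "AAA", year = 2010, gender = c("male", "female"),
    population = pop / 2, fha_incidence = c(cf_male, cf_female),
    births = births
  ))
  econ <- economics_table(data.frame(
    country = "AAA", year = 2010, gdp_pc_ppp = gdp, us_gdp_pc_ppp = us_gdp
  ))
  list(intake = intake, concentrations = conc, demographics = demo,
       economics = econ, farm_fractions = NULL)
}

# Independent resolution of one concentration (base-R, mirrors the stated
# rules: country rows first, GLOBAL fallback, geometric farm/wild mixture).
oracle_conc <- function(conc, ctry, cat, bin, f) {
  sel_bin <- if (is.na(bin)) is.na(conc$bin) else !is.na(conc$bin) & conc$bin == bin
  rows <- conc[conc$country == ctry & conc$category == cat & sel_bin, ]
  if (nrow(rows) == 0) {
    rows <- conc[conc$country == "GLOBAL" & conc$category == cat & sel_bin, ]
  }
  if (any(rows$origin == "all")) {
    rows$concentration[rows$origin == "all"][1]
  } else if (any(rows$origin == "farm") && any(rows$origin == "wild")) {
    cf <- rows$concentration[rows$origin == "farm"][1]
    cw <- rows$concentration[rows$origin == "wild"][1]
    exp(f * log(cf) + (1 - f) * log(cw))
  } else {
    rows$concentration[1]
  }
}

oracle_farm_fraction <- function(world, ctry, cat) {
  ff <- world$farm_fractions
  if (is.null(ff)) return(0)
  sel <- ff$country == ctry & ff$category == cat
  if (!any(sel)) 0 else ff$farm_fraction[which(sel)[1]]
}

# Triple-loop exposure recomputation for one country.
oracle_exposure <- function(world, ctry) {
  rows <- world$intake[world$intake$country == ctry, ]
  E <- c(seafood = 0, freshwater_fish = 0, rice = 0)
  for (i in seq_len(nrow(rows))) {
    f <- oracle_farm_fraction(world, ctry, rows$category[i])
    cc <- oracle_conc(world$concentrations, ctry, rows$category[i], rows$bin[i], f)
    E[[rows$category[i]]] <- E[[rows$category[i]]] + rows$intake[i] * cc
  }
  E
}

# Straight-line global recomputation: exposure -> IQ/FHA -> valuation for
# one year (with pathway ratios), plus cumulative discounting over years.
oracle_global_loss <- function(world, year, ratios = c(seafood = 1, freshwater_fish = 1, rice = 1),
                               gamma = 0.3, lambda = 0.2, beta = 0.6,
                               phi = 0.066, omega = 0.33,
                               iq_value = 18832, vsl = 6.3e6) {
  countries <- unique(world$intake$country)
  tot <- c(iq = 0, deaths = 0, loss = 0)
  for (ctry in countries) {
    E0 <- oracle_exposure(world, ctry)
    E <- sum(E0 * ratios[names(E0)])
    demo <- world$demographics
    dsel <- demo$country == ctry & demo$year == year
    wcf <- sum(demo$population[dsel] * demo$fha_incidence[dsel])
    births <- demo$births[dsel][1]
    iq <- gamma * lambda * beta * E * births
    deaths <- wcf * omega * (1 - exp(-phi * lambda * beta * E))
    econ <- world$economics
    esel <- econ$country == ctry & econ$year == year
    ratio <- econ$gdp_pc_ppp[esel][1] / econ$us_gdp_pc_ppp[esel][1]
    tot <- tot + c(iq = iq, deaths = deaths,
                   loss = (iq * iq_value + deaths * vsl) * ratio)
  }
  tot
}

oracle_traj_ratios <- function(world, scenario, year) {
  tr <- world$trajectories
  sel <- tr$scenario == scenario & tr$country == "GLOBAL"
  v <- function(col, yr) tr[[col]][sel & tr$year == yr][1]
  c(seafood = v("P", year) / v("P", 2010),
    freshwater_fish = v("D", year) / v("D", 2010),
    rice = v("S", year) / v("S", 2010))
}

oracle_cumulative <- function(world, scenario, years, rate = 0.03, horizon = 2050) {
  total <- 0
  for (y in years) {
    r <- oracle_traj_ratios(world, scenario, y)
    g <- oracle_global_loss(world, y, ratios = r)
    total <- total + g[["loss"]] * (1 + rate)^(horizon - y)
  }
  total
}
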