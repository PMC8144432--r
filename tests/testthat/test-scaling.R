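test_that("anchor interpolation is linear, exact at anchors, and refuses extrapolation", {
  defs <- scenario_definitions()
  mfr <- defs[defs$scenario == "MFR", ]
  expect_equal(interpolate_anchors(mfr, 2030), 1095) # midpoint of 1890 and 300
  expect_equal(interpolate_anchors(mfr, 2010), 1890)
  cp <- defs[defs$scenario == "CP", ]
  expect_equal(interpolate_anchors(cp, 2035), 1960)
  expect_error(interpolate_anchors(mfr, 2051), "extrapolation")
  expect_error(interpolate_anchors(mfr, 2009), "extrapolation")
})

flat_traj <- function(scenario = "CP", D = 1, S = 1, P = 1, years = c(2010, 2030, 2050)) {
  trajectory_table(tidyr::expand_grid(scenario = scenario, country = "GLOBAL",
                                      year = years) |>
                     dplyr::mutate(D = D, S = S, P = P))
}

test_that("identity proxies leave the concentration table unchanged", {
  w <- tiny_world()
  out <- scale_concentrations(w$concentrations, flat_traj(), "AAA", 2030)
  expect_equal(out$concentration, w$concentrations$concentration)
})

test_that("each pathway is scaled by its own proxy ratio", {
  w <- tiny_world()
  traj <- trajectory_table(data.frame(
    scenario = "MFR", country = "GLOBAL", year = c(2010, 2050),
    D = c(1, 0.52), S = c(1, 0.97), P = c(1, 0.76)
  ))
  out <- scale_concentrations(w$concentrations, traj, "AAA", 2050)
  base <- w$concentrations
  expect_equal(out$concentration[out$category == "freshwater_fish"],
               0.52 * base$concentration[base$category == "freshwater_fish"])
  expect_equal(out$concentration[out$category == "rice"],
               0.97 * base$concentration[base$category == "rice"])
  expect_equal(out$concentration[out$category == "seafood"],
               0.76 * base$concentration[base$category == "seafood"])
})

test_that("country D and S series take precedence; P stays global", {
  w <- tiny_world()
  traj <- trajectory_table(dplyr::bind_rows(
    data.frame(scenario = "X", country = "GLOBAL", year = c(2010, 2050),
               D = c(1, 2), S = c(1, 2), P = c(1, 0.5)),
    data.frame(scenario = "X", country = "AAA", year = c(2010, 2050),
               D = c(1, 3), S = c(1, 4), P = c(1, 99))
  ))
  out <- scale_concentrations(w$concentrations, traj, "AAA", 2050)
  base <- w$concentrations
  expect_equal(out$concentration[out$category == "freshwater_fish"],
               3 * base$concentration[base$category == "freshwater_fish"])
  expect_equal(out$concentration[out$category == "rice"],
               4 * base$concentration[base$category == "rice"])
  # seafood is scaled by the global plankton series, not the country column
  expect_equal(out$concentration[out$category == "seafood"],
               0.5 * base$concentration[base$category == "seafood"])
})

test_that("scaling composes: direct to y2 equals via y1 then y2/y1", {
  cfg <- synthetic_world_config(n_countries = 4, seed = 8)
  w <- generate_world(cfg)
  traj <- w$trajectories[w$trajectories$scenario == "MFR", ]
  ctry <- w$countries$country[1]
  direct <- scale_concentrations(w$concentrations, traj, ctry, 2050)

  via <- scale_concentrations(w$concentrations, traj, ctry, 2030)
  # renormalise the trajectory at 2030 so its ratios become y/2030
  renorm <- traj[traj$year >= 2030, ]
  renorm$year[renorm$year == 2030] <- 2010
  two_step <- scale_concentrations(via, trajectory_table(renorm), ctry, 2050)
  expect_equal(two_step$concentration, direct$concentration, tolerance = 1e-12)
})

test_that("decreasing all proxies decreases every country's total exposure", {
  w <- generate_world(synthetic_world_config(n_countries = 5, seed = 13))
  traj <- trajectory_table(data.frame(
    scenario = "down", country = "GLOBAL", year = c(2010, 2050),
    D = c(1, 0.8), S = c(1, 0.9), P = c(1, 0.7)
  ))
  for (ctry in w$countries$country) {
    base <- compute_exposure(w$intake, w$concentrations, ctry,
                             farm_fractions = w$farm_fractions, quiet = TRUE)
    scaled <- scale_concentrations(w$concentrations, traj, ctry, 2050)
    after <- compute_exposure(w$intake, scaled, ctry,
                              farm_fractions = w$farm_fractions, quiet = TRUE)
    expect_lt(after$total, base$total)
  }
})

test_that("zero or negative 2010 proxies are rejected", {
  w <- tiny_world()
  traj <- data.frame(scenario = "X", country = "GLOBAL", year = c(2010, 2050),
                     D = c(0, 1), S = c(1, 1), P = c(1, 1))
  expect_error(trajectory_table(traj), "> 0")
  # bypassing the constructor still trips the division guard
  expect_error(scale_concentrations(w$concentrations, traj, "AAA", 2050), "> 0")
})

test_that("built-in emission scenarios carry the printed anchors", {
  defs <- scenario_definitions()
  pick <- function(sc, yr) defs$emission[defs$scenario == sc & defs$year == yr]
  expect_equal(pick("CP", 2010), 1890)
  expect_equal(pick("MFR", 2050), 300)
  expect_equal(pick("NP-Delayed", 2050), 1020)
  expect_equal(pick("A1B", 2050), 4900)
  expect_equal(pick("A2", 2050), 3900)
})
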