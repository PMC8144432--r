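test_that("worlds are reproducible under a fixed seed and differ across seeds", {
  cfg <- synthetic_world_config(n_countries = 8, seed = 17)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  for (el in c("intake", "concentrations", "demographics", "economics",
               "trajectories")) {
    expect_identical(w1[[el]], w2[[el]])
  }
  w3 <- generate_world(synthetic_world_config(n_countries = 8, seed = 18))
  expect_false(identical(w1$intake, w3$intake))
})

test_that("generated tables pass every downstream validator", {
  w <- generate_world(synthetic_world_config(n_countries = 10, seed = 30))
  expect_silent(intake_table(w$intake))
  expect_silent(concentration_table(w$concentrations))
  expect_silent(demographics_table(w$demographics))
  expect_silent(economics_table(w$economics))
  expect_silent(trajectory_table(w$trajectories))
  # cross-table keys line up
  expect_setequal(unique(w$intake$country), w$countries$country)
  expect_setequal(unique(w$demographics$country), w$countries$country)
  expect_setequal(unique(w$economics$country), w$countries$country)
})

test_that("concentrations span ~10x between the lowest and highest trophic bins", {
  w <- generate_world(synthetic_world_config(n_countries = 20, seed = 41))
  for (cat in c("seafood", "freshwater_fish")) {
    conc <- w$concentrations
    rows <- conc[conc$category == cat & conc$country != "GLOBAL", ]
    gm <- tapply(log(rows$concentration), rows$bin, mean)
    ratio <- exp(gm[["4.5-5"]] - gm[["2-2.5"]])
    expect_gte(ratio, 8)
    expect_lte(ratio, 12)
  }
})

test_that("the island anchor country reproduces the record seafood exposure", {
  w <- generate_world(synthetic_world_config(n_countries = 12, seed = 6))
  anchor <- w$countries$country[w$countries$archetype == "island"][1]
  res <- compute_exposure(w$intake, w$concentrations, anchor,
                          farm_fractions = w$farm_fractions, quiet = TRUE)
  expect_equal(res$seafood, 33, tolerance = 1e-9)
  # and it tops the per-fetus IQ ranking
  base <- run_baseline(w)
  expect_equal(base$country[which.max(base$per_fetus_iq)], anchor)
})

test_that("global pathway shares land near 56/34/10 under the default mix", {
  w <- generate_world(synthetic_world_config())
  res <- compute_exposure_all(w$intake, w$concentrations,
                              farm_fractions = w$farm_fractions)
  pop <- w$countries$population[match(res$country, w$countries$country)]
  shares <- c(
    seafood = sum(res$seafood * pop),
    freshwater_fish = sum(res$freshwater_fish * pop),
    rice = sum(res$rice * pop)
  )
  shares <- 100 * shares / sum(shares)
  expect_lt(abs(shares[["seafood"]] - 56), 10)
  expect_lt(abs(shares[["freshwater_fish"]] - 34), 10)
  expect_lt(abs(shares[["rice"]] - 10), 10)
})

test_that("the default world reproduces the global burden anchors to order of magnitude", {
  w <- generate_world(synthetic_world_config())
  g <- attr(run_baseline(w), "global")
  # ~1.2e7 IQ points (0.086/fetus), ~29,000 deaths, ~$117B per year
  expect_gt(g$total_iq, 1.2e7 / 2); expect_lt(g$total_iq, 1.2e7 * 2)
  expect_gt(g$per_fetus_iq, 0.086 / 2); expect_lt(g$per_fetus_iq, 0.086 * 2)
  expect_gt(g$fha_deaths, 29000 / 2); expect_lt(g$fha_deaths, 29000 * 2)
  expect_gt(g$total_usd, 117e9 / 3); expect_lt(g$total_usd, 117e9 * 3)
})

test_that("scenario trajectories anchor 2010 at 1 and 2050 at the configured response", {
  cfg <- synthetic_world_config()
  traj <- generate_scenario_trajectories(cfg)
  at <- function(sc, yr, col) traj[[col]][traj$scenario == sc & traj$year == yr]
  for (sc in names(cfg$deposition_response)) {
    expect_equal(at(sc, 2010, "D"), 1)
    expect_equal(at(sc, 2010, "S"), 1)
    expect_equal(at(sc, 2010, "P"), 1)
    expect_equal(at(sc, 2050, "D"), cfg$deposition_response[[sc]], tolerance = 1e-9)
    expect_equal(at(sc, 2050, "S"), cfg$soil_response[[sc]], tolerance = 1e-9)
  }
  # CP is the flat reference; MFR/A1B carry the printed 2050 deposition responses
  expect_true(all(at("CP", cfg$years, "D") == 1))
  expect_equal(at("MFR", 2050, "D"), 0.52)
  expect_equal(at("A1B", 2050, "D"), 1.87)
  # plankton response is the dampened deposition response
  expect_equal(at("MFR", 2050, "P"), 1 + 0.5 * (0.52 - 1), tolerance = 1e-9)
  # trajectories are monotone between the endpoints
  d <- at("MFR", cfg$years, "D")
  expect_true(all(diff(d) < 0))
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_world_config(n_countries = 0), ">= 1")
  arch <- synthetic_world_config()$archetypes
  arch$count_share <- c(0.5, 0.5, 0.5)
  expect_error(synthetic_world_config(archetypes = arch), "sum to 1")
  expect_error(
    synthetic_world_config(bin_fractions = list(seafood = c(1, 0, 0, 0),
                                                freshwater_fish = c(0.5, 0.5, 0.5, 0))),
    "summing to 1"
  )
  expect_error(
    synthetic_world_config(deposition_response = c(MFR = 0.5)),
    "CP"
  )
})
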