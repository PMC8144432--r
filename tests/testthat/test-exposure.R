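test_that("exposure is the hand-computed sum of intake times concentration", {
  w <- tiny_world()
  res <- compute_exposure(w$intake, w$concentrations, "AAA")
  # seafood 10 g/d x 0.1 ug/g + FW fish 5 x 0.2 + rice 200 x 0.005
  expect_equal(res$seafood, 1.0)
  expect_equal(res$freshwater_fish, 1.0)
  expect_equal(res$rice, 1.0)
  expect_equal(res$total, 3.0)
})

test_that("zero intakes give zero exposure", {
  w <- tiny_world()
  w$intake$intake <- 0
  res <- compute_exposure(w$intake, w$concentrations, "AAA")
  expect_equal(res$total, 0)
})

test_that("exposure is additive and homogeneous in intakes and concentrations", {
  w <- generate_world(synthetic_world_config(n_countries = 6, seed = 3))
  res <- compute_exposure_all(w$intake, w$concentrations,
                              farm_fractions = w$farm_fractions)
  expect_equal(res$total, res$seafood + res$freshwater_fish + res$rice,
               tolerance = 1e-12)

  w2 <- w
  w2$intake$intake <- 2 * w2$intake$intake
  res2 <- compute_exposure_all(w2$intake, w2$concentrations,
                               farm_fractions = w2$farm_fractions)
  expect_equal(res2$total, 2 * res$total, tolerance = 1e-12)

  w3 <- w
  w3$concentrations$concentration <- 2 * w3$concentrations$concentration
  res3 <- compute_exposure_all(w3$intake, w3$concentrations,
                               farm_fractions = w3$farm_fractions)
  expect_equal(res3$total, 2 * res$total, tolerance = 1e-12)
})

test_that("GLOBAL fallback: dropping a country's records yields the GLOBAL result", {
  w <- generate_world(synthetic_world_config(n_countries = 6, seed = 5))
  ctry <- w$countries$country[2]
  before <- compute_exposure(w$intake, w$concentrations, ctry,
                             farm_fractions = w$farm_fractions, quiet = TRUE)

  stripped <- w$concentrations[w$concentrations$country != ctry, ]
  expect_message(
    after <- compute_exposure(w$intake, stripped, ctry,
                              farm_fractions = w$farm_fractions),
    "GLOBAL"
  )
  # equals the same computation done against GLOBAL rows only
  global_only <- w$concentrations[w$concentrations$country == "GLOBAL", ]
  ref <- compute_exposure(w$intake, global_only, ctry,
                          farm_fractions = w$farm_fractions, quiet = TRUE)
  expect_equal(after$total, ref$total, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(before$total, after$total)))
})

test_that("missing key after GLOBAL fallback is a hard error naming the key", {
  w <- tiny_world()
  conc <- w$concentrations[w$concentrations$category != "rice", ]
  expect_error(
    compute_exposure(w$intake, concentration_table(conc, require_global = FALSE), "AAA"),
    "rice"
  )
  expect_error(compute_exposure(w$intake, w$concentrations, "ZZZ"), "ZZZ")
})

test_that("farm/wild origins combine as a farm-fraction-weighted geometric mixture", {
  intake <- intake_table(data.frame(
    country = "AAA", category = "seafood", bin = "3.5-4.5", intake = 10
  ))
  conc <- concentration_table(data.frame(
    country = "GLOBAL", category = "seafood", bin = "3.5-4.5",
    origin = c("farm", "wild"), concentration = c(0.05, 0.2)
  ))
  f <- 0.3
  res <- compute_exposure(intake, conc, "AAA", farm_fractions = f)
  expect_equal(res$seafood, 10 * exp(f * log(0.05) + (1 - f) * log(0.2)),
               tolerance = 1e-12)
  # f = 0 reduces to wild; f = 1 to farm
  expect_equal(compute_exposure(intake, conc, "AAA", farm_fractions = 0)$seafood, 2)
  expect_equal(compute_exposure(intake, conc, "AAA", farm_fractions = 1)$seafood, 0.5)
})

test_that("pipeline exposure matches an independent triple-loop recomputation", {
  set.seed(91)
  bins <- trophic_bins()$bin
  for (rep in 1:100) {
    n <- sample(2:4, 1)
    countries <- sprintf("C%02d", seq_len(n))
    intake <- dplyr::bind_rows(
      tidyr::expand_grid(country = countries, category = c("seafood", "freshwater_fish"),
                         bin = bins),
      tidyr::expand_grid(country = countries, category = "rice", bin = NA_character_)
    )
    intake$intake <- runif(nrow(intake), 0, 50)
    conc <- tidyr::expand_grid(
      country = c(sample(countries, n - 1), "GLOBAL"), # one country relies on fallback
      category = c("seafood", "freshwater_fish"),
      bin = bins, origin = c("farm", "wild")
    )
    conc$concentration <- exp(runif(nrow(conc), log(0.005), log(0.5)))
    rice <- tidyr::expand_grid(country = c(countries, "GLOBAL"), category = "rice",
                               bin = NA_character_, origin = "all")
    rice$concentration <- exp(runif(nrow(rice), log(0.001), log(0.01)))
    world <- list(
      intake = intake_table(intake),
      concentrations = concentration_table(dplyr::bind_rows(conc, rice)),
      farm_fractions = tidyr::expand_grid(country = countries,
                                          category = c("seafood", "freshwater_fish")) |>
        dplyr::mutate(farm_fraction = runif(dplyr::n()))
    )
    res <- compute_exposure_all(world$intake, world$concentrations,
                                farm_fractions = world$farm_fractions)
    for (i in seq_len(n)) {
      expect_equal(res$total[res$country == countries[i]],
                   sum(oracle_exposure(world, countries[i])),
                   tolerance = 1e-10)
    }
  }
})
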