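# one-country world with no FHA mortality: the annual loss is then exactly
# linear in the consumption multiplier, giving an analytic reference
linear_toy_world <- function() {
  w <- tiny_world(cf_male = 0, cf_female = 0)
  w$trajectories <- trajectory_table(data.frame(
    scenario = "CP", country = "GLOBAL", year = 2010, D = 1, S = 1, P = 1
  ))
  w
}

test_that("degenerate spec collapses the Monte Carlo onto the point estimate", {
  w <- linear_toy_world()
  spec <- uncertainty_spec(n_draws = 50, seed = 4, vary = character(0))
  mc <- run_monte_carlo(w, spec, statistic = "annual_loss")
  expect_equal(mc$ci_low, mc$point)
  expect_equal(mc$ci_high, mc$point)
  expect_true(all(mc$draws == mc$point))
})

test_that("draws are bit-identical for identical (seed, spec, world)", {
  w <- generate_world(synthetic_world_config(n_countries = 4, seed = 2))
  spec <- uncertainty_spec(n_draws = 40, seed = 123)
  a <- run_monte_carlo(w, spec)
  b <- run_monte_carlo(w, spec)
  expect_identical(a$draws, b$draws)
  expect_identical(c(a$ci_low, a$ci_high), c(b$ci_low, b$ci_high))
  # a different seed moves the draws
  c_ <- run_monte_carlo(w, uncertainty_spec(n_draws = 40, seed = 124))
  expect_false(identical(a$draws, c_$draws))
})

test_that("sample_parameters reproduces the bundle used for a given draw", {
  spec <- uncertainty_spec(n_draws = 10, seed = 9)
  s3a <- sample_parameters(spec, draw = 3)
  s3b <- sample_parameters(spec, draw = 3)
  expect_identical(s3a, s3b)
  s4 <- sample_parameters(spec, draw = 4)
  expect_false(identical(s3a$dr$gamma, s4$dr$gamma))
  # degenerate spec returns the point parameters
  d <- sample_parameters(uncertainty_spec(vary = character(0)), draw = 1)
  expect_equal(d$dr$gamma, 0.3)
  expect_equal(d$vsl, 6.3e6)
  expect_true(all(d$intake_mult == 1))
})

test_that("sampled values respect their declared supports", {
  spec <- uncertainty_spec(n_draws = 2000, seed = 31)
  vsls <- omegas <- iqvs <- numeric(0)
  set.seed(spec$seed)
  keys <- list(countries = "X",
               conc_groups = tibble::tibble(category = "all", bin = NA, gsd = 1.3))
  for (i in 1:2000) {
    b <- mehgrisk:::draw_bundle(spec, keys, dose_response_params(), valuation_params())
    vsls[i] <- b$vsl; omegas[i] <- b$dr$omega; iqvs[i] <- b$iq_value
  }
  expect_gte(min(vsls), 1e6)
  expect_lte(max(vsls), 1e7)
  # log-uniform: both halves of the log-range are visited
  expect_gt(mean(vsls < sqrt(1e6 * 1e7)), 0.4)
  expect_setequal(unique(omegas), c(0.165, 0.495))
  expect_setequal(unique(iqvs), c(8013, 18832))
})

test_that("a single log-normal factor propagates to its analytic quantiles", {
  w <- linear_toy_world()
  sdlog <- log(2) / (2 * qnorm(0.975))
  spec <- uncertainty_spec(n_draws = 1000, seed = 77, vary = "consumption",
                           intake_sdlog = sdlog)
  mc <- run_monte_carlo(w, spec, statistic = "annual_loss")
  for (p in c(0.025, 0.975)) {
    analytic <- mc$point * exp(sdlog * qnorm(p))
    emp <- unname(quantile(mc$draws, p, type = 7))
    # 3 Monte Carlo standard errors of the order statistic
    q <- exp(sdlog * qnorm(p))
    dens <- dnorm(qnorm(p)) / (q * sdlog)
    se <- sqrt(p * (1 - p) / 1000) / dens * mc$point
    expect_lt(abs(emp - analytic), 3 * se)
  }
  # the 95% range spans a factor of ~2 by construction
  expect_equal(mc$ci_high / mc$ci_low, 2, tolerance = 0.1)
})

test_that("one-factor envelopes isolate their group and dose-response is widest", {
  w <- generate_world(synthetic_world_config(n_countries = 8, seed = 21))
  spec <- uncertainty_spec(n_draws = 300, seed = 5)
  fs <- factor_sensitivity(w, spec)
  expect_setequal(fs$factor, c("consumption", "concentration", "dose_response",
                               "valuation", "overall"))
  widths <- setNames(fs$width, fs$factor)
  expect_gt(widths[["dose_response"]], widths[["consumption"]])
  expect_gt(widths[["dose_response"]], widths[["concentration"]])
  expect_gt(widths[["dose_response"]], widths[["valuation"]])
  # joint variation should not be much narrower than its widest component
  # (equality only in expectation; allow quantile noise at n = 300)
  expect_gte(widths[["overall"]], 0.8 * widths[["dose_response"]])
  # degenerate spec collapses all envelopes
  fs0 <- factor_sensitivity(w, uncertainty_spec(n_draws = 5, seed = 5,
                                                vary = character(0)))
  expect_equal(fs0$width, rep(0, 5))
  expect_equal(fs0$ci_low, rep(attr(fs0, "point"), 5))
})

test_that("enlarging a factor's dispersion never narrows the overall CI", {
  for (seed in 1:10) {
    w <- generate_world(synthetic_world_config(n_countries = 3, seed = seed))
    base <- uncertainty_spec(n_draws = 200, seed = 50 + seed)
    wide <- uncertainty_spec(n_draws = 200, seed = 50 + seed,
                             intake_sdlog = 2 * base$intake_sdlog,
                             gamma_cv = 2 * base$gamma_cv)
    a <- run_monte_carlo(w, base, statistic = "annual_loss")
    b <- run_monte_carlo(w, wide, statistic = "annual_loss")
    expect_lte(b$ci_low, a$ci_low + 1e-9 * abs(a$ci_low))
    expect_gte(b$ci_high, a$ci_high - 1e-9 * abs(a$ci_high))
  }
})

test_that("invalid uncertainty specifications are rejected at construction", {
  expect_error(uncertainty_spec(n_draws = 0), ">= 1")
  expect_error(uncertainty_spec(vary = "diet"), "subset")
  expect_error(uncertainty_spec(omega_values = c(0.1, 1.5)), "probabilities")
  expect_error(uncertainty_spec(vsl_range = c(1e7, 1e6)), "increasing")
})
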