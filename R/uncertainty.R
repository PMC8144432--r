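# Monte Carlo propagation of the four factor-group uncertainties:
# food consumption, food MeHg concentrations, dose-response parameters, and
# economic valuation. Each draw perturbs the groups jointly (or one at a
# time for sensitivity envelopes), re-evaluates the full exposure -> health
# -> valuation pipeline, and the 2.5/97.5 percentiles of the draws give the
# 95% confidence interval.

#' Specification of the Monte Carlo uncertainty analysis
#'
#' @param n_draws Number of pipeline evaluations (default 1000).
#' @param seed RNG seed; draws are a deterministic function of
#'   (seed, spec, world).
#' @param vary Character subset of
#'   `c("consumption", "concentration", "dose_response", "valuation")`
#'   naming the factor groups that are sampled; groups not listed are held
#'   at their point values (an empty vector gives a degenerate spec).
#' @param intake_sdlog Log-scale SD of the per-country consumption
#'   multiplier. The default makes the 95% range span a factor of 2
#'   (`log(2) / (2 * qnorm(0.975))`), matching the agreement between
#'   food-balance and national survey data.
#' @param conc_gsd_default Geometric SD used for concentration groups whose
#'   table rows carry no `gsd` (default 1.3).
#' @param beta_cv,lambda_cv Coefficients of variation of the pharmacokinetic
#'   coefficients (truncated normal at zero; defaults 0.15, i.e. the stated
#'   10--20% variability).
#' @param gamma_cv,phi_cv Coefficients of variation of the IQ and
#'   fatal-heart-attack effect coefficients (defaults 0.5, reflecting their
#'   dominant contribution to overall uncertainty).
#' @param omega_values Two-point support for the probability of causality
#'   (default 0.5x and 1.5x the point value 0.33).
#' @param iq_values Two-point support for the USD value per IQ point
#'   (default `c(8013, 18832)`).
#' @param vsl_range Log-uniform support for the value of statistical life
#'   (default 1e6 to 1e7 USD).
#' @return A list of class `"uncertainty_spec"`.
#' @export
uncertainty_spec <- function(n_draws = 1000, seed = 1,
                             vary = c("consumption", "concentration",
                                      "dose_response", "valuation"),
                             intake_sdlog = log(2) / (2 * qnorm(0.975)),
                             conc_gsd_default = 1.3,
                             beta_cv = 0.15, lambda_cv = 0.15,
                             gamma_cv = 0.5, phi_cv = 0.5,
                             omega_values = c(0.165, 0.495),
                             iq_values = c(8013, 18832),
                             vsl_range = c(1e6, 1e7)) {
  groups <- c("consumption", "concentration", "dose_response", "valuation")
  if (!is.numeric(n_draws) || n_draws < 1) abort("`n_draws` must be >= 1.")
  if (length(vary) > 0 && !all(vary %in% groups)) {
    abort(sprintf("`vary` must be a subset of: %s.", paste(groups, collapse = ", ")))
  }
  cvs <- c(intake_sdlog = intake_sdlog, beta_cv = beta_cv, lambda_cv = lambda_cv,
           gamma_cv = gamma_cv, phi_cv = phi_cv)
  if (any(!is.finite(cvs)) || any(cvs < 0)) {
    abort("Dispersion parameters must be finite and >= 0.")
  }
  if (conc_gsd_default < 1) abort("`conc_gsd_default` must be >= 1.")
  if (length(omega_values) != 2 || any(omega_values < 0) || any(omega_values > 1)) {
    abort("`omega_values` must be two probabilities.")
  }
  if (length(iq_values) != 2 || any(iq_values <= 0)) {
    abort("`iq_values` must be two positive values.")
  }
  if (length(vsl_range) != 2 || any(vsl_range <= 0) || vsl_range[1] > vsl_range[2]) {
    abort("`vsl_range` must be an increasing pair of positive values.")
  }
  structure(
    list(n_draws = as.integer(n_draws), seed = seed, vary = vary,
         intake_sdlog = intake_sdlog, conc_gsd_default = conc_gsd_default,
         beta_cv = beta_cv, lambda_cv = lambda_cv, gamma_cv = gamma_cv,
         phi_cv = phi_cv, omega_values = sort(omega_values),
         iq_values = sort(iq_values), vsl_range = vsl_range),
    class = "uncertainty_spec"
  )
}

# one truncated-normal (at zero) draw; consumes exactly one uniform
rtnorm1 <- function(mean, cv) {
  s <- mean * cv
  if (s == 0) {
    runif(1) # keep the RNG stream aligned across degenerate specs
    return(mean)
  }
  qnorm(runif(1, pnorm(0, mean, s), 1), mean, s)
}

# keys describing the world's sampling granularity: countries for the
# consumption multiplier, (category, bin) groups for concentrations
world_sampling_keys <- function(world, spec) {
  conc <- world$concentrations
  groups <- conc |>
    dplyr::group_by(.data$category, .data$bin) |>
    dplyr::summarise(
      gsd = {
        g <- .data$gsd[!is.na(.data$gsd)]
        if (length(g) == 0) spec$conc_gsd_default else exp(mean(log(g)))
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$category, .data$bin)
  list(countries = sort(unique(world$intake$country)), conc_groups = groups)
}

# draw one parameter bundle; RNG call count is independent of `vary` and of
# the dispersion values so that seeds stay comparable across specs
draw_bundle <- function(spec, keys, dr_point, val_point) {
  nc <- length(keys$countries)
  ng <- nrow(keys$conc_groups)
  intake_mult <- rlnorm(nc, 0, spec$intake_sdlog)
  conc_mult <- rlnorm(ng, 0, log(keys$conc_groups$gsd))
  beta <- rtnorm1(dr_point$beta, spec$beta_cv)
  lambda <- rtnorm1(dr_point$lambda, spec$lambda_cv)
  gamma <- rtnorm1(dr_point$gamma, spec$gamma_cv)
  phi <- rtnorm1(dr_point$phi, spec$phi_cv)
  omega <- spec$omega_values[sample.int(2, 1)]
  iq_value <- spec$iq_values[sample.int(2, 1)]
  lv <- log(spec$vsl_range)
  vsl <- exp(runif(1, lv[1], lv[2]))
  if (!"consumption" %in% spec$vary) intake_mult[] <- 1
  if (!"concentration" %in% spec$vary) conc_mult[] <- 1
  if (!"dose_response" %in% spec$vary) {
    beta <- dr_point$beta; lambda <- dr_point$lambda
    gamma <- dr_point$gamma; phi <- dr_point$phi; omega <- dr_point$omega
  }
  if (!"valuation" %in% spec$vary) {
    iq_value <- val_point$iq_value; vsl <- val_point$vsl
  }
  list(
    intake_mult = setNames(intake_mult, keys$countries),
    conc_mult = conc_mult,
    dr = dose_response_params(beta, lambda, gamma, phi, omega, dr_point$bw),
    iq_value = iq_value,
    vsl = vsl
  )
}

#' Sample the parameter bundle of a given Monte Carlo draw
#'
#' Reproduces exactly the bundle that [run_monte_carlo()] uses for draw
#' `draw` under the same spec and world: the generator is seeded with
#' `spec$seed` and advanced draw by draw.
#'
#' @param spec An [uncertainty_spec()].
#' @param draw Draw index in `1:n_draws`.
#' @param world Optional world (as from [generate_world()]) defining the
#'   sampling granularity; without it a single consumption multiplier and a
#'   single concentration group at the default geometric SD are sampled.
#' @param dr,val Point parameter objects.
#' @return A list with elements `intake_mult`, `conc_mult`, `dr`
#'   (a [dose_response_params()]), `iq_value`, `vsl`.
#' @export
sample_parameters <- function(spec, draw = 1, world = NULL,
                              dr = dose_response_params(),
                              val = valuation_params()) {
  if (draw < 1 || draw > spec$n_draws) {
    abort(sprintf("`draw` must lie in 1..%d.", spec$n_draws))
  }
  keys <- if (is.null(world)) {
    list(countries = "GLOBAL",
         conc_groups = tibble::tibble(category = "all", bin = NA_character_,
                                      gsd = spec$conc_gsd_default))
  } else {
    world_sampling_keys(world, spec)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)
  for (i in seq_len(draw - 1)) draw_bundle(spec, keys, dr, val)
  draw_bundle(spec, keys, dr, val)
}

# Precompute everything the per-draw pipeline evaluation needs as matrices
# (years x countries), so each draw is a handful of vectorised operations.
build_mc_evaluator <- function(world, dr, val,
                               statistic = c("cumulative_loss", "annual_loss"),
                               scenario = "CP",
                               conc_gsd_default = 1.3) {
  statistic <- match.arg(statistic)
  countries <- sort(unique(world$intake$country))
  years <- if (statistic == "cumulative_loss") {
    sort(unique(world$demographics$year))
  } else {
    2010L
  }
  if (!2010 %in% years) abort("Demographics must include 2010.")

  # bin-level base exposure matrix: countries x (category, bin) groups
  groups <- world$concentrations |>
    dplyr::group_by(.data$category, .data$bin) |>
    dplyr::summarise(
      gsd = {
        g <- .data$gsd[!is.na(.data$gsd)]
        if (length(g) == 0) conc_gsd_default else exp(mean(log(g)))
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$category, .data$bin)
  gkey <- paste(groups$category, groups$bin, sep = "|")
  B <- matrix(0, length(countries), nrow(groups),
              dimnames = list(countries, gkey))
  for (ctry in countries) {
    br <- exposure_breakdown(world$intake, world$concentrations, ctry,
                             world$farm_fractions, quiet = TRUE)
    k <- paste(br$category, br$bin, sep = "|")
    for (i in seq_len(nrow(br))) B[ctry, k[i]] <- B[ctry, k[i]] + br$exposure[i]
  }
  sf_cols <- which(groups$category == "seafood")
  fw_cols <- which(groups$category == "freshwater_fish")
  rice_cols <- which(groups$category == "rice")

  # demographic and economic matrices
  mat_from <- function(df, value) {
    wide <- df |>
      dplyr::select(dplyr::all_of(c("country", "year", value))) |>
      tidyr::pivot_wider(names_from = "country", values_from = dplyr::all_of(value))
    wide <- wide[wide$year %in% years, , drop = FALSE]
    wide <- wide[order(wide$year), , drop = FALSE]
    m <- as.matrix(wide[, countries, drop = FALSE])
    if (any(is.na(m))) {
      abort(sprintf("Missing `%s` for some (country, year) needed by the pipeline.", value))
    }
    rownames(m) <- wide$year
    m
  }
  demo_cy <- world$demographics |>
    dplyr::group_by(.data$country, .data$year) |>
    dplyr::summarise(
      wcf = sum(.data$population * .data$fha_incidence),
      births = .data$births[1],
      .groups = "drop"
    )
  wcf <- mat_from(demo_cy, "wcf")
  births <- mat_from(demo_cy, "births")
  econ <- world$economics |>
    dplyr::mutate(ratio = .data$gdp_pc_ppp / .data$us_gdp_pc_ppp)
  gdpr <- mat_from(econ, "ratio")

  # pathway scaling ratio matrices for the chosen scenario
  if (statistic == "cumulative_loss") {
    traj <- world$trajectories[world$trajectories$scenario == scenario, , drop = FALSE]
    if (nrow(traj) == 0) abort(sprintf("Scenario `%s` not in the trajectory table.", scenario))
    traj_countries <- setdiff(unique(traj$country), "GLOBAL")
    ratio_for <- function(ctry) {
      key <- if (ctry %in% traj_countries) ctry else "GLOBAL"
      pathway_ratios(traj, key, years)
    }
    shared <- if (length(traj_countries) == 0) ratio_for("GLOBAL") else NULL
    rl <- lapply(countries, function(ctry) shared %||% ratio_for(ctry))
    Rsf <- vapply(rl, function(r) r$seafood, numeric(length(years)))
    Rfw <- vapply(rl, function(r) r$freshwater_fish, numeric(length(years)))
    Rrice <- vapply(rl, function(r) r$rice, numeric(length(years)))
    if (length(years) == 1) {
      Rsf <- matrix(Rsf, 1); Rfw <- matrix(Rfw, 1); Rrice <- matrix(Rrice, 1)
    }
  } else {
    one <- matrix(1, length(years), length(countries))
    Rsf <- Rfw <- Rrice <- one
  }
  disc <- (1 + val$discount_rate)^(val$horizon_year - years)

  keys <- list(countries = countries, conc_groups = groups)

  evaluate <- function(bundle) {
    mi <- bundle$intake_mult[countries]
    mc <- bundle$conc_mult
    drp <- bundle$dr
    Esf <- as.vector(B[, sf_cols, drop = FALSE] %*% mc[sf_cols]) * mi
    Efw <- as.vector(B[, fw_cols, drop = FALSE] %*% mc[fw_cols]) * mi
    Erice <- as.vector(B[, rice_cols, drop = FALSE] %*% mc[rice_cols]) * mi
    # years x countries exposure under the scenario's proportional scaling
    E <- Rsf * rep(Esf, each = length(years)) +
      Rfw * rep(Efw, each = length(years)) +
      Rrice * rep(Erice, each = length(years))
    iq <- drp$gamma * drp$lambda * drp$beta * E * births
    deaths <- wcf * drp$omega * (1 - exp(-drp$phi * drp$lambda * drp$beta * E))
    loss <- (iq * bundle$iq_value * val$deflator_2008 +
               deaths * bundle$vsl * val$deflator_2005) * gdpr
    annual <- rowSums(loss)
    if (statistic == "cumulative_loss") sum(annual * disc) else annual[[which(years == 2010)]]
  }

  list(evaluate = evaluate, keys = keys, years = years)
}

point_bundle <- function(keys, dr, val) {
  list(
    intake_mult = setNames(rep(1, length(keys$countries)), keys$countries),
    conc_mult = rep(1, nrow(keys$conc_groups)),
    dr = dr, iq_value = val$iq_value, vsl = val$vsl
  )
}

#' Run the Monte Carlo uncertainty analysis
#'
#' Repeats the full exposure-to-valuation pipeline `n_draws` times with
#' parameters sampled per [uncertainty_spec()], and summarises the draws by
#' the 2.5th and 97.5th percentiles (linear interpolation between order
#' statistics, quantile type 7).
#'
#' @param world A world list (as from [generate_world()] or [read_world()]).
#' @param spec An [uncertainty_spec()].
#' @param dr,val Point parameter objects.
#' @param statistic `"cumulative_loss"` (discounted 2010--2050 global loss
#'   under `scenario`, the default) or `"annual_loss"` (global loss in 2010).
#' @param scenario Scenario for the cumulative statistic (default `"CP"`).
#' @return A list of class `"mc_result"`: `point`, `draws`, `ci_low`,
#'   `ci_high`, `n_draws`, `statistic`, `scenario`, `spec`.
#' @export
run_monte_carlo <- function(world, spec = uncertainty_spec(),
                            dr = dose_response_params(),
                            val = valuation_params(),
                            statistic = c("cumulative_loss", "annual_loss"),
                            scenario = "CP") {
  statistic <- match.arg(statistic)
  ev <- build_mc_evaluator(world, dr, val, statistic, scenario,
                           conc_gsd_default = spec$conc_gsd_default)
  point <- ev$evaluate(point_bundle(ev$keys, dr, val))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)
  draws <- vapply(seq_len(spec$n_draws), function(i) {
    bundle <- draw_bundle(spec, ev$keys, dr, val)
    out <- ev$evaluate(bundle)
    if (!is.finite(out)) {
      abort(sprintf("Pipeline evaluation failed at draw %d (non-finite result).", i))
    }
    out
  }, numeric(1))

  ci <- unname(quantile(draws, c(0.025, 0.975), type = 7))
  structure(
    list(point = point, draws = draws, ci_low = ci[1], ci_high = ci[2],
         n_draws = spec$n_draws, statistic = statistic, scenario = scenario,
         spec = spec),
    class = "mc_result"
  )
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo %s (%s, %d draws):\n  point %.4g, 95%% CI [%.4g, %.4g]\n",
    x$statistic, x$scenario, x$n_draws, x$point, x$ci_low, x$ci_high
  ))
  invisible(x)
}

#' One-factor-at-a-time sensitivity envelopes
#'
#' For each of the four factor groups, reruns the Monte Carlo with only that
#' group varying (others at point values) and reports the resulting 95%
#' envelope of the pipeline statistic, alongside the all-factors overall
#' interval.
#'
#' @inheritParams run_monte_carlo
#' @return Tibble with columns `factor` (`"consumption"`,
#'   `"concentration"`, `"dose_response"`, `"valuation"`, `"overall"`),
#'   `ci_low`, `ci_high`, `width`; the point estimate is attached as
#'   attribute `"point"`.
#' @export
factor_sensitivity <- function(world, spec = uncertainty_spec(),
                               dr = dose_response_params(),
                               val = valuation_params(),
                               statistic = c("cumulative_loss", "annual_loss"),
                               scenario = "CP") {
  statistic <- match.arg(statistic)
  groups <- c("consumption", "concentration", "dose_response", "valuation")
  rows <- purrr::map_dfr(c(groups, "overall"), function(g) {
    sp <- spec
    # honour degeneracy requested in `spec`: a group outside spec$vary stays
    # at its point values even in its own envelope run
    sp$vary <- if (g == "overall") spec$vary else intersect(spec$vary, g)
    mc <- run_monte_carlo(world, sp, dr, val, statistic, scenario)
    tibble::tibble(factor = g, ci_low = mc$ci_low, ci_high = mc$ci_high,
                   width = mc$ci_high - mc$ci_low)
  })
  point <- run_monte_carlo(
    world, {sp <- spec; sp$vary <- character(0); sp$n_draws <- 1L; sp},
    dr, val, statistic, scenario
  )$point
  attr(rows, "point") <- point
  rows
}
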