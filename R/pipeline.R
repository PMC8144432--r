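# End-to-end drivers tying the stages together: a present-day baseline
# assessment per country, scenario projections of the global burden to 2050,
# and the Monte Carlo uncertainty report.

#' Present-day baseline health-impact assessment
#'
#' For every country in the world's intake table: dietary MeHg exposure by
#' pathway, per-fetus and total IQ decrements, attributable fatal heart
#' attacks, implied blood/hair biomarkers, and monetised losses, ranked by
#' total loss.
#'
#' @param world A world list (as from [generate_world()] or [read_world()]).
#' @param dr A [dose_response_params()] object.
#' @param val A [valuation_params()] object.
#' @param year Assessment year (default 2010); demographics and economics
#'   must cover it.
#' @param measured_biomarkers Optional data frame with columns `country` and
#'   `blood` (measured ug/L) for biomarker evaluation.
#' @return Tibble with one row per country (exposure pathways, `total`
#'   exposure, `per_fetus_iq`, `total_iq`, `fha_deaths`, `blood`, `hair`,
#'   `iq_loss_usd`, `fha_loss_usd`, `total_usd`), sorted by decreasing
#'   `total_usd`. Attributes: `"global"` (list of global totals) and, when
#'   measured data were supplied, `"biomarker_eval"` (see
#'   [evaluate_biomarkers()]).
#' @export
run_baseline <- function(world, dr = dose_response_params(),
                         val = valuation_params(), year = 2010,
                         measured_biomarkers = NULL) {
  expo <- compute_exposure_all(world$intake, world$concentrations,
                               year = year,
                               farm_fractions = world$farm_fractions)
  demo <- world$demographics[world$demographics$year == year, , drop = FALSE]
  if (nrow(demo) == 0) abort(sprintf("Demographics lack year %d.", year))

  res <- purrr::map_dfr(seq_len(nrow(expo)), function(i) {
    ctry <- expo$country[i]
    E <- expo$total[i]
    d <- demo[demo$country == ctry, , drop = FALSE]
    if (nrow(d) == 0) abort(sprintf("Demographics lack country %s in %d.", ctry, year))
    pf <- per_fetus_iq(E, dr)
    tiq <- total_iq_loss(pf, d)
    deaths <- fha_deaths(E, d, dr)
    bm <- biomarkers(E, dr)
    tibble::tibble(
      country = ctry,
      per_fetus_iq = pf,
      total_iq = tiq,
      fha_deaths = deaths,
      blood = bm$blood,
      hair = bm$hair,
      iq_loss_usd = iq_monetary_loss(tiq, world$economics, ctry, year, val),
      fha_loss_usd = fha_monetary_loss(deaths, world$economics, ctry, year, val)
    )
  })
  out <- dplyr::left_join(expo, res, by = "country") |>
    dplyr::mutate(total_usd = .data$iq_loss_usd + .data$fha_loss_usd) |>
    dplyr::arrange(dplyr::desc(.data$total_usd))

  births_total <- demo |>
    dplyr::distinct(.data$country, .data$births) |>
    dplyr::pull(.data$births) |>
    sum()
  attr(out, "global") <- list(
    year = year,
    total_iq = sum(out$total_iq),
    per_fetus_iq = sum(out$total_iq) / births_total,
    fha_deaths = sum(out$fha_deaths),
    iq_loss_usd = sum(out$iq_loss_usd),
    fha_loss_usd = sum(out$fha_loss_usd),
    total_usd = sum(out$total_usd)
  )
  if (!is.null(measured_biomarkers)) {
    merged <- dplyr::inner_join(
      out[, c("country", "blood")],
      measured_biomarkers[, c("country", "blood")],
      by = "country", suffix = c("_pred", "_meas")
    )
    attr(out, "biomarker_eval") <-
      evaluate_biomarkers(merged$blood_pred, merged$blood_meas)
  }
  out
}

# shared ratio table for a scenario: country, year, pathway multipliers
scenario_ratio_table <- function(traj, countries, years) {
  traj_countries <- setdiff(unique(traj$country), "GLOBAL")
  if (length(traj_countries) == 0) {
    shared <- pathway_ratios(traj, "GLOBAL", years)
    return(tidyr::expand_grid(country = countries, shared))
  }
  purrr::map_dfr(countries, function(ctry) {
    key <- if (ctry %in% traj_countries) ctry else "GLOBAL"
    dplyr::bind_cols(country = ctry, pathway_ratios(traj, key, years))
  })
}

#' Project global health burdens under emission scenarios
#'
#' Holds food consumption constant, scales 2010 concentrations with each
#' scenario's environmental proxy trajectories, and combines the resulting
#' exposure with the demographic and economic trajectories into yearly
#' global totals plus the discounted cumulative loss at the horizon.
#'
#' @inheritParams run_baseline
#' @param scenarios Scenarios to project; default all in the world's
#'   trajectory table.
#' @param years Years to evaluate; default all demographic years.
#' @return A list of class `"scenario_projection"`: `annual` (tibble with
#'   `scenario`, `year`, `total_iq`, `fha_deaths`, `iq_loss_usd`,
#'   `fha_loss_usd`, `total_usd`) and `cumulative` (tibble with `scenario`,
#'   `cumulative_usd`, the losses compounded to the horizon year).
#' @export
run_scenarios <- function(world, scenarios = NULL, years = NULL,
                          dr = dose_response_params(),
                          val = valuation_params()) {
  scenarios <- scenarios %||% unique(world$trajectories$scenario)
  years <- years %||% sort(unique(world$demographics$year))
  missing <- setdiff(scenarios, unique(world$trajectories$scenario))
  if (length(missing) > 0) {
    abort(sprintf("Scenario(s) not in the trajectory table: %s.",
                  paste(missing, collapse = ", ")))
  }

  base <- compute_exposure_all(world$intake, world$concentrations,
                               farm_fractions = world$farm_fractions)
  demo_cy <- world$demographics |>
    dplyr::filter(.data$year %in% years) |>
    dplyr::group_by(.data$country, .data$year) |>
    dplyr::summarise(
      wcf = sum(.data$population * .data$fha_incidence),
      births = .data$births[1],
      .groups = "drop"
    )
  econ <- world$economics |>
    dplyr::mutate(gdp_ratio = .data$gdp_pc_ppp / .data$us_gdp_pc_ppp) |>
    dplyr::select(dplyr::all_of(c("country", "year", "gdp_ratio")))

  annual <- purrr::map_dfr(scenarios, function(sc) {
    traj <- world$trajectories[world$trajectories$scenario == sc, , drop = FALSE]
    ratios <- scenario_ratio_table(traj, base$country, years)
    df <- ratios |>
      dplyr::inner_join(
        base |>
          dplyr::select(dplyr::all_of(c("country", "seafood", "freshwater_fish", "rice"))),
        by = "country", suffix = c("_r", "")
      ) |>
      dplyr::mutate(
        exposure = .data$seafood * .data$seafood_r +
          .data$freshwater_fish * .data$freshwater_fish_r +
          .data$rice * .data$rice_r
      ) |>
      dplyr::inner_join(demo_cy, by = c("country", "year")) |>
      dplyr::inner_join(econ, by = c("country", "year")) |>
      dplyr::mutate(
        iq = dr$gamma * dr$lambda * dr$beta * .data$exposure * .data$births,
        deaths = .data$wcf * dr$omega *
          (1 - exp(-dr$phi * dr$lambda * dr$beta * .data$exposure)),
        iq_loss = .data$iq * val$iq_value * val$deflator_2008 * .data$gdp_ratio,
        fha_loss = .data$deaths * val$vsl * val$deflator_2005 * .data$gdp_ratio
      )
    df |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(
        total_iq = sum(.data$iq),
        fha_deaths = sum(.data$deaths),
        iq_loss_usd = sum(.data$iq_loss),
        fha_loss_usd = sum(.data$fha_loss),
        .groups = "drop"
      ) |>
      dplyr::mutate(scenario = sc, total_usd = .data$iq_loss_usd + .data$fha_loss_usd) |>
      dplyr::select(dplyr::all_of(c("scenario", "year", "total_iq", "fha_deaths",
                                    "iq_loss_usd", "fha_loss_usd", "total_usd")))
  })

  cumulative <- annual |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(
      cumulative_usd = discount_to_horizon(
        data.frame(year = .data$year, loss = .data$total_usd),
        rate = val$discount_rate, horizon = val$horizon_year,
        convention = val$convention
      ),
      .groups = "drop"
    )

  structure(list(annual = annual, cumulative = cumulative),
            class = "scenario_projection")
}

#' @export
print.scenario_projection <- function(x, ...) {
  cat("Scenario projection of global MeHg health burden\n")
  cat(sprintf("  years %d-%d, scenarios: %s\n",
              min(x$annual$year), max(x$annual$year),
              paste(unique(x$annual$scenario), collapse = ", ")))
  cat("  cumulative discounted loss at horizon (USD):\n")
  for (i in seq_len(nrow(x$cumulative))) {
    cat(sprintf("    %-11s %.4g\n", x$cumulative$scenario[i],
                x$cumulative$cumulative_usd[i]))
  }
  invisible(x)
}

#' Monte Carlo uncertainty report
#'
#' Runs the overall (all-factors) Monte Carlo and the one-factor-at-a-time
#' sensitivity envelopes for the chosen pipeline statistic.
#'
#' @inheritParams run_monte_carlo
#' @param include_factors Also compute the four per-factor envelopes
#'   (default TRUE; quadruples the run time).
#' @return A list of class `"uncertainty_report"`: `overall` (an
#'   `"mc_result"`), `factors` (tibble or NULL), `statistic`, `scenario`.
#' @export
run_uncertainty <- function(world, spec = uncertainty_spec(),
                            dr = dose_response_params(),
                            val = valuation_params(),
                            statistic = c("cumulative_loss", "annual_loss"),
                            scenario = "CP", include_factors = TRUE) {
  statistic <- match.arg(statistic)
  overall <- run_monte_carlo(world, spec, dr, val, statistic, scenario)
  factors <- if (include_factors) {
    fs <- factor_sensitivity(world, spec, dr, val, statistic, scenario)
    fs[fs$factor != "overall", , drop = FALSE]
  } else {
    NULL
  }
  structure(
    list(overall = overall, factors = factors, statistic = statistic,
         scenario = scenario),
    class = "uncertainty_report"
  )
}

#' @export
print.uncertainty_report <- function(x, ...) {
  print(x$overall)
  if (!is.null(x$factors)) {
    cat("  one-factor-at-a-time envelopes:\n")
    for (i in seq_len(nrow(x$factors))) {
      cat(sprintf("    %-14s [%.4g, %.4g]\n", x$factors$factor[i],
                  x$factors$ci_low[i], x$factors$ci_high[i]))
    }
  }
  invisible(x)
}
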