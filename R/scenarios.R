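# Emission scenarios and proportional scaling of concentration tables.
#
# Future food MeHg concentrations are obtained by scaling the 2010 table with
# environmental proxy ratios: freshwater fish follow the country's
# atmospheric Hg deposition (D), rice follows the country's soil Hg
# concentration (S), and seafood follows the global harvest-weighted plankton
# MeHg concentration (P):
#   C_year^fw   = C_2010^fw   * D_year / D_2010
#   C_year^rice = C_2010^rice * S_year / S_2010
#   C_year^sea  = C_2010^sea  * P_year / P_2010

#' Built-in global anthropogenic Hg emission scenarios, 2010--2050
#'
#' Anchor points (year, global primary anthropogenic Hg emission in Mg/yr)
#' for the five policy scenarios: CP (current policy, near-constant), that
#' serves as the reference; NP-Delayed (new-policy goal delayed to 2050);
#' MFR (maximum feasible reduction); and the growth scenarios A1B (business
#' as usual) and A2 (divided world). All scenarios share the 2010 inventory
#' of 1890 Mg/yr.
#'
#' @return Tibble with columns `scenario`, `year`, `emission` (Mg/yr),
#'   sorted by scenario and year.
#' @export
#' @examples
#' scenario_definitions()
scenario_definitions <- function() {
  tibble::tribble(
    ~scenario,    ~year, ~emission,
    "CP",          2010,      1890,
    "CP",          2035,      1960,
    "CP",          2050,      1960,
    "NP-Delayed",  2010,      1890,
    "NP-Delayed",  2050,      1020,
    "MFR",         2010,      1890,
    "MFR",         2050,       300,
    "A1B",         2010,      1890,
    "A1B",         2050,      4900,
    "A2",          2010,      1890,
    "A2",          2050,      3900
  )
}

#' Piecewise-linear interpolation between scenario anchors
#'
#' @param anchors Data frame with columns `year` and `emission` (or a second
#'   numeric column named `value`), sorted or sortable by year; at least two
#'   anchors.
#' @param year Year(s) at which to evaluate; must lie within the anchor span
#'   (no extrapolation).
#' @return Interpolated value(s), exact at anchors.
#' @export
#' @examples
#' mfr <- subset(scenario_definitions(), scenario == "MFR")
#' interpolate_anchors(mfr, 2030)
interpolate_anchors <- function(anchors, year) {
  anchors <- tibble::as_tibble(anchors)
  vcol <- intersect(c("emission", "value"), names(anchors))[1]
  if (!"year" %in% names(anchors) || is.na(vcol)) {
    abort("`anchors` needs a `year` column and an `emission` (or `value`) column.")
  }
  anchors <- anchors[order(anchors$year), , drop = FALSE]
  if (nrow(anchors) < 2) abort("Need at least two anchors to interpolate.")
  if (any(anchors[[vcol]] <= 0)) abort("Anchor values must be > 0.")
  rng <- range(anchors$year)
  if (any(year < rng[1] | year > rng[2])) {
    abort(sprintf(
      "Year(s) %s outside the anchor span [%d, %d]; extrapolation is not supported.",
      paste(year[year < rng[1] | year > rng[2]], collapse = ", "), rng[1], rng[2]
    ))
  }
  approx(anchors$year, anchors[[vcol]], xout = year, method = "linear")$y
}

# Proxy ratios (year vs 2010) for one country in a single-scenario
# trajectory, with GLOBAL fallback per proxy. P is always global.
proxy_ratios <- function(traj, country, year) {
  if (length(unique(traj$scenario)) != 1) {
    abort("`traj` must contain a single scenario; filter before scaling.")
  }
  series_value <- function(ctry, yr, col) {
    sel <- traj$country == ctry & traj$year == yr
    if (!any(sel)) return(NA_real_)
    traj[[col]][which(sel)[1]]
  }
  ratio_for <- function(col, ctry) {
    v1 <- series_value(ctry, year, col)
    v0 <- series_value(ctry, 2010, col)
    if (is.na(v1) || is.na(v0)) {
      v1 <- series_value("GLOBAL", year, col)
      v0 <- series_value("GLOBAL", 2010, col)
    }
    if (is.na(v1) || is.na(v0)) {
      abort(sprintf(
        "Trajectory lacks `%s` for %s (and GLOBAL) in year %d and/or 2010.",
        col, ctry, year
      ))
    }
    if (v0 <= 0) abort(sprintf("2010 proxy `%s` must be > 0 for normalisation.", col))
    v1 / v0
  }
  c(
    D = ratio_for("D", country),
    S = ratio_for("S", country),
    P = ratio_for("P", "GLOBAL")
  )
}

#' Scale a 2010 concentration table to a future year
#'
#' Applies the proportional scaling rules: freshwater-fish records are
#' multiplied by the country's atmospheric-deposition ratio D_year/D_2010,
#' rice records by the country's soil-Hg ratio S_year/S_2010, and seafood
#' records by the global plankton-MeHg ratio P_year/P_2010. Rows for other
#' countries than `country`/`GLOBAL` are dropped; all other fields are
#' untouched.
#'
#' @param base A validated 2010 concentration table.
#' @param traj A validated single-scenario trajectory table containing 2010
#'   and the target year (country rows or GLOBAL fallback).
#' @param country Country whose D and S ratios apply.
#' @param year Target year.
#' @return A concentration table for `year` restricted to `country` and
#'   GLOBAL rows.
#' @export
scale_concentrations <- function(base, traj, country, year) {
  r <- proxy_ratios(traj, country, year)
  out <- base[base$country %in% c(country, "GLOBAL"), , drop = FALSE]
  mult <- c(seafood = r[["P"]], freshwater_fish = r[["D"]], rice = r[["S"]])
  out$concentration <- out$concentration * unname(mult[out$category])
  out
}

#' Pathway scaling ratios for a set of years
#'
#' Convenience wrapper used by the scenario pipeline: for each requested
#' year, the multiplicative factor that the proportional-scaling rules apply
#' to each exposure pathway of `country` (seafood via global plankton,
#' freshwater fish via country deposition, rice via country soil Hg).
#'
#' @inheritParams scale_concentrations
#' @param years Vector of target years.
#' @return Tibble with columns `year`, `seafood`, `freshwater_fish`, `rice`.
#' @export
pathway_ratios <- function(traj, country, years) {
  purrr::map_dfr(years, function(y) {
    r <- proxy_ratios(traj, country, y)
    tibble::tibble(
      year = y,
      seafood = r[["P"]],
      freshwater_fish = r[["D"]],
      rice = r[["S"]]
    )
  })
}
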