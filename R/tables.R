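# Input tables are plain tibbles with a fixed column contract; the
# constructors below validate and normalise them. Intakes are carried
# internally in g/person/day; concentrations in ug MeHg per g food.

KG_PER_YEAR_TO_G_PER_DAY <- 1000 / 365.25

#' Convert annual per-capita consumption to daily grams
#'
#' Food-balance data (FAO convention) report kg/person/year; the exposure
#' model works in g/person/day.
#'
#' @param kg_per_year Numeric vector, kg/person/year.
#' @return g/person/day.
#' @export
#' @examples
#' kg_per_year_to_g_per_day(15) # global average seafood consumption
kg_per_year_to_g_per_day <- function(kg_per_year) {
  kg_per_year * KG_PER_YEAR_TO_G_PER_DAY
}

#' Construct and validate a food-intake table
#'
#' One row per (country, category, trophic bin): per-capita intake in
#' g/person/day. Rice carries no trophic bin (`bin` is NA); fish categories
#' must use the labels of [trophic_bins()].
#'
#' @param x Data frame with columns `country` (ISO3 or synthetic code),
#'   `category` (one of `"seafood"`, `"freshwater_fish"`, `"rice"`),
#'   `bin` (bin label or NA for rice), `intake` (g/person/day, >= 0).
#' @return A validated tibble.
#' @export
intake_table <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("country", "category", "bin", "intake")
  if (!all(need %in% names(x))) {
    abort(sprintf("Intake table needs columns: %s.", paste(need, collapse = ", ")))
  }
  if (!all(x$category %in% .categories)) {
    abort(sprintf(
      "Unknown food category: %s.",
      paste(unique(setdiff(x$category, .categories)), collapse = ", ")
    ))
  }
  if (any(!is.finite(x$intake) | x$intake < 0)) {
    abort("All intakes must be finite and >= 0 (g/person/day).")
  }
  rice <- x$category == "rice"
  if (any(!is.na(x$bin[rice]))) {
    abort("Rice intake records must not carry a trophic bin.")
  }
  if (any(is.na(x$bin[!rice])) || !all(x$bin[!rice] %in% trophic_bins()$bin)) {
    abort("Fish intake records must carry a valid trophic bin label.")
  }
  dup <- duplicated(x[, c("country", "category", "bin")])
  if (any(dup)) {
    abort("Duplicate (country, category, bin) rows in intake table.")
  }
  x
}

#' Construct and validate a concentration table
#'
#' One row per (country-or-GLOBAL, category, trophic bin, origin): geometric
#' mean MeHg concentration in ug/g, plus a geometric standard deviation used
#' by the uncertainty module. `origin` is `"wild"`/`"farm"` for fish
#' categories (or `"all"` when undifferentiated) and `"all"` for rice. A
#' `"GLOBAL"` record must exist for every (category, bin, origin) present so
#' that the country fallback never fails.
#'
#' @param x Data frame with columns `country`, `category`, `bin`, `origin`,
#'   `concentration` (> 0, ug/g), and optionally `gsd` (> 1 or NA).
#' @param require_global Check that a GLOBAL fallback record exists for every
#'   (category, bin, origin) combination present (default TRUE).
#' @return A validated tibble (with a `gsd` column, NA-filled if absent).
#' @export
concentration_table <- function(x, require_global = TRUE) {
  x <- tibble::as_tibble(x)
  need <- c("country", "category", "bin", "origin", "concentration")
  if (!all(need %in% names(x))) {
    abort(sprintf("Concentration table needs columns: %s.", paste(need, collapse = ", ")))
  }
  if (!"gsd" %in% names(x)) x$gsd <- NA_real_
  if (!all(x$category %in% .categories)) {
    abort(sprintf(
      "Unknown food category: %s.",
      paste(unique(setdiff(x$category, .categories)), collapse = ", ")
    ))
  }
  if (!all(x$origin %in% c("wild", "farm", "all"))) {
    abort("`origin` must be one of \"wild\", \"farm\", \"all\".")
  }
  if (any(!is.finite(x$concentration) | x$concentration <= 0)) {
    abort("All concentrations must be finite and > 0 (ug MeHg per g food).")
  }
  if (any(!is.na(x$gsd) & x$gsd < 1)) {
    abort("Geometric standard deviations must be >= 1 (or NA).")
  }
  rice <- x$category == "rice"
  if (any(!is.na(x$bin[rice]))) {
    abort("Rice concentration records must not carry a trophic bin.")
  }
  if (any(is.na(x$bin[!rice])) || !all(x$bin[!rice] %in% trophic_bins()$bin)) {
    abort("Fish concentration records must carry a valid trophic bin label.")
  }
  if (require_global) {
    keys <- unique(x[, c("category", "bin", "origin")])
    glob <- x[x$country == "GLOBAL", c("category", "bin", "origin")]
    missing <- dplyr::anti_join(keys, glob, by = c("category", "bin", "origin"))
    if (nrow(missing) > 0) {
      abort(sprintf(
        "No GLOBAL fallback record for: %s.",
        paste(sprintf("(%s, %s, %s)", missing$category, missing$bin, missing$origin),
              collapse = "; ")
      ))
    }
  }
  x
}

#' Construct and validate a demographic trajectory table
#'
#' Long format: one row per (country, year, gender) with the population of
#' that gender, its age-adjusted fatal-heart-attack incidence (deaths per
#' person per year), and the country's annual newborns (repeated on both
#' gender rows).
#'
#' @param x Data frame with columns `country`, `year`, `gender`
#'   (`"male"`/`"female"`), `population`, `fha_incidence`, `births`.
#' @return A validated tibble.
#' @export
demographics_table <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("country", "year", "gender", "population", "fha_incidence", "births")
  if (!all(need %in% names(x))) {
    abort(sprintf("Demographics table needs columns: %s.", paste(need, collapse = ", ")))
  }
  if (!all(x$gender %in% c("male", "female"))) {
    abort("`gender` must be \"male\" or \"female\".")
  }
  num <- c("population", "fha_incidence", "births")
  for (col in num) {
    if (any(!is.finite(x[[col]]) | x[[col]] < 0)) {
      abort(sprintf("`%s` must be finite and >= 0.", col))
    }
  }
  both <- x |>
    dplyr::count(.data$country, .data$year) |>
    dplyr::filter(.data$n != 2)
  if (nrow(both) > 0) {
    abort(sprintf(
      "Each (country, year) needs exactly one male and one female row; offending: %s.",
      paste(sprintf("%s/%d", both$country, both$year), collapse = ", ")
    ))
  }
  x
}

#' Construct and validate an economic trajectory table
#'
#' @param x Data frame with columns `country`, `year`, `gdp_pc_ppp`
#'   (PPP-adjusted per-capita GDP, USD) and `us_gdp_pc_ppp` (the US value for
#'   the same year, the denominator of the benefit-transfer ratio).
#' @return A validated tibble.
#' @export
economics_table <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("country", "year", "gdp_pc_ppp", "us_gdp_pc_ppp")
  if (!all(need %in% names(x))) {
    abort(sprintf("Economics table needs columns: %s.", paste(need, collapse = ", ")))
  }
  if (any(!is.finite(x$gdp_pc_ppp) | x$gdp_pc_ppp <= 0) ||
      any(!is.finite(x$us_gdp_pc_ppp) | x$us_gdp_pc_ppp <= 0)) {
    abort("GDP per capita values must be finite and > 0.")
  }
  x
}

#' Construct and validate an environmental trajectory table
#'
#' Yearly environmental proxies per scenario and country (or `"GLOBAL"`):
#' `D` atmospheric Hg deposition, `S` soil Hg concentration, `P`
#' harvest-weighted plankton MeHg. All are used as ratios against their 2010
#' value, so relative (2010 = 1) or absolute units are both acceptable; a
#' 2010 row must exist for every (scenario, country) series.
#'
#' @param x Data frame with columns `scenario`, `country`, `year`, `D`, `S`, `P`.
#' @return A validated tibble.
#' @export
trajectory_table <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("scenario", "country", "year", "D", "S", "P")
  if (!all(need %in% names(x))) {
    abort(sprintf("Trajectory table needs columns: %s.", paste(need, collapse = ", ")))
  }
  for (col in c("D", "S", "P")) {
    if (any(!is.finite(x[[col]]) | x[[col]] <= 0)) {
      abort(sprintf("Proxy `%s` must be finite and > 0 everywhere.", col))
    }
  }
  no2010 <- x |>
    dplyr::group_by(.data$scenario, .data$country) |>
    dplyr::summarise(has2010 = any(.data$year == 2010), .groups = "drop") |>
    dplyr::filter(!.data$has2010)
  if (nrow(no2010) > 0) {
    abort(sprintf(
      "Missing 2010 normalisation row for: %s.",
      paste(sprintf("%s/%s", no2010$scenario, no2010$country), collapse = ", ")
    ))
  }
  x
}

#' Write a world (set of input tables) to a directory of CSV files
#'
#' Writes `intake.csv`, `concentrations.csv`, `demographics.csv`,
#' `economics.csv`, `trajectories.csv` and a `manifest.json` recording units
#' and, for synthetic worlds, the generating seed and configuration echo.
#'
#' @param world A list as produced by [generate_world()] (or with the same
#'   element names).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(world$intake, file.path(dir, "intake.csv"))
  readr::write_csv(world$concentrations, file.path(dir, "concentrations.csv"))
  readr::write_csv(world$demographics, file.path(dir, "demographics.csv"))
  readr::write_csv(world$economics, file.path(dir, "economics.csv"))
  readr::write_csv(world$trajectories, file.path(dir, "trajectories.csv"))
  if (!is.null(world$farm_fractions)) {
    readr::write_csv(world$farm_fractions, file.path(dir, "farm_fractions.csv"))
  }
  manifest <- list(
    units = list(
      intake = "g/person/day",
      concentration = "ug MeHg per g food (geometric mean)",
      population = "persons",
      fha_incidence = "deaths per person per year",
      gdp_pc_ppp = "USD (PPP)",
      proxies = "relative to 2010"
    ),
    provenance = if (!is.null(world$config)) "synthetic (generate_world)" else "user-supplied",
    seed = world$config$seed %||% NULL,
    n_countries = length(unique(world$intake$country))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' Read a world written by [write_world()]
#'
#' @param dir Directory containing the CSV tables.
#' @return A list with validated elements `intake`, `concentrations`,
#'   `demographics`, `economics`, `trajectories`, and `manifest`.
#' @export
read_world <- function(dir) {
  rd <- function(f) readr::read_csv(file.path(dir, f), show_col_types = FALSE,
                                    progress = FALSE)
  out <- list(
    intake = intake_table(rd("intake.csv")),
    concentrations = concentration_table(rd("concentrations.csv")),
    demographics = demographics_table(rd("demographics.csv")),
    economics = economics_table(rd("economics.csv")),
    trajectories = trajectory_table(rd("trajectories.csv")),
    manifest = jsonlite::read_json(file.path(dir, "manifest.json"))
  )
  ff <- file.path(dir, "farm_fractions.csv")
  if (file.exists(ff)) out$farm_fractions <- rd("farm_fractions.csv")
  out
}
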