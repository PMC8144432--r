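# Exposure aggregation: E = sum_i I_i C_i over freshwater fish and seafood
# trophic bins, plus I*C for rice, per country, in ug MeHg/person/day.

# Resolve the concentration for one (country, category, bin) key, falling
# back to the GLOBAL record and combining farm/wild origins geometrically.
resolve_concentration <- function(conc, country, category, bin, farm_fraction,
                                  quiet = FALSE) {
  pick <- function(ctry) {
    sel <- conc$country == ctry & conc$category == category &
      (if (is.na(bin)) is.na(conc$bin) else !is.na(conc$bin) & conc$bin == bin)
    conc[sel, , drop = FALSE]
  }
  rows <- pick(country)
  source <- "country"
  if (nrow(rows) == 0) {
    rows <- pick("GLOBAL")
    source <- "global"
    if (nrow(rows) == 0) {
      abort(sprintf(
        "No concentration record (country or GLOBAL) for (%s, %s, %s).",
        country, category, ifelse(is.na(bin), "-", bin)
      ))
    }
    if (!quiet) {
      inform(sprintf(
        "Using GLOBAL mean concentration for %s (%s, %s).",
        country, category, ifelse(is.na(bin), "-", bin)
      ))
    }
  }
  has <- function(o) any(rows$origin == o)
  val <- function(o) rows$concentration[rows$origin == o][1]
  value <- if (has("all")) {
    val("all")
  } else if (has("farm") && has("wild")) {
    # farm-fraction-weighted geometric mixture preserves geometric-mean semantics
    exp(farm_fraction * log(val("farm")) + (1 - farm_fraction) * log(val("wild")))
  } else if (has("wild")) {
    val("wild")
  } else {
    val("farm")
  }
  list(concentration = value, source = source)
}

# farm fraction lookup: tibble(country, category, farm_fraction) or scalar
lookup_farm_fraction <- function(farm_fractions, country, category, default = 0) {
  if (is.null(farm_fractions)) return(default)
  if (is.numeric(farm_fractions) && length(farm_fractions) == 1) {
    return(farm_fractions)
  }
  sel <- farm_fractions$country == country & farm_fractions$category == category
  if (!any(sel)) return(default)
  farm_fractions$farm_fraction[which(sel)[1]]
}

#' Per-record breakdown of a country's dietary MeHg exposure
#'
#' Joins the country's intake records against resolved concentrations
#' (country-specific where available, GLOBAL geometric means otherwise;
#' farm/wild origins combined by the country's farm fraction) and returns one
#' row per intake record with its exposure contribution.
#'
#' @param intake A validated intake table (see [intake_table()]).
#' @param conc A validated concentration table (see [concentration_table()]).
#' @param country Country code present in `intake`.
#' @param farm_fractions Optional farm-fraction lookup: a tibble with columns
#'   `country`, `category`, `farm_fraction`, or a single number applied
#'   everywhere. Defaults to 0 (all wild) where unspecified.
#' @param quiet Suppress GLOBAL-fallback messages (default FALSE).
#' @return Tibble with columns `country`, `category`, `bin`, `intake`,
#'   `concentration`, `source` (`"country"`/`"global"`), `exposure`
#'   (ug/person/day).
#' @export
exposure_breakdown <- function(intake, conc, country, farm_fractions = NULL,
                               quiet = FALSE) {
  rows <- intake[intake$country == country, , drop = FALSE]
  if (nrow(rows) == 0) {
    abort(sprintf("Country `%s` has no intake records.", country))
  }
  res <- purrr::pmap(
    list(rows$category, rows$bin, rows$intake),
    function(category, bin, ig) {
      f <- lookup_farm_fraction(farm_fractions, country, category)
      r <- resolve_concentration(conc, country, category, bin, f, quiet = quiet)
      tibble::tibble(
        concentration = r$concentration,
        source = r$source,
        exposure = ig * r$concentration
      )
    }
  )
  dplyr::bind_cols(
    rows[, c("country", "category", "bin", "intake")],
    dplyr::bind_rows(res)
  )
}

#' Total dietary MeHg exposure for one country
#'
#' Computes the per-capita daily methylmercury exposure as the sum over
#' trophic-level bins of intake times concentration for freshwater fish and
#' seafood, plus the rice term.
#'
#' @inheritParams exposure_breakdown
#' @param year Calendar year to stamp on the result (the tables themselves
#'   are year-specific; default 2010).
#' @return One-row tibble: `country`, `year`, `seafood`, `freshwater_fish`,
#'   `rice` (pathway exposures) and `total`, all in ug/person/day.
#' @export
#' @examples
#' intake <- intake_table(data.frame(
#'   country = "AAA", category = c("seafood", "rice"),
#'   bin = c("3.5-4.5", NA), intake = c(10, 200)
#' ))
#' conc <- concentration_table(data.frame(
#'   country = "GLOBAL", category = c("seafood", "rice"),
#'   bin = c("3.5-4.5", NA), origin = "all", concentration = c(0.1, 0.005)
#' ))
#' compute_exposure(intake, conc, "AAA")
compute_exposure <- function(intake, conc, country, year = 2010,
                             farm_fractions = NULL, quiet = FALSE) {
  br <- exposure_breakdown(intake, conc, country, farm_fractions, quiet = quiet)
  path <- vapply(
    .categories,
    function(cat) sum(br$exposure[br$category == cat]),
    numeric(1)
  )
  tibble::tibble(
    country = country,
    year = year,
    seafood = path[["seafood"]],
    freshwater_fish = path[["freshwater_fish"]],
    rice = path[["rice"]],
    total = sum(path)
  )
}

#' Total dietary MeHg exposure for many countries
#'
#' @inheritParams compute_exposure
#' @param countries Countries to evaluate; defaults to all countries in the
#'   intake table.
#' @return Tibble with one row per country (see [compute_exposure()]).
#' @export
compute_exposure_all <- function(intake, conc, countries = NULL, year = 2010,
                                 farm_fractions = NULL, quiet = TRUE) {
  countries <- countries %||% unique(intake$country)
  purrr::map_dfr(
    countries,
    function(ctry) compute_exposure(intake, conc, ctry, year, farm_fractions,
                                    quiet = quiet)
  )
}
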