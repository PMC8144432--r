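# Economic valuation: IQ decrements are monetised at a fixed USD value per
# point, fatal heart attacks by a value of statistical life (VSL). Both unit
# values are US-based and are transferred to other countries by the ratio of
# PPP-adjusted per-capita GDP to the US value (unit income elasticity).
# Annual losses over 2010-2050 are accumulated to the 2050 horizon with
# compound discounting.

#' Economic valuation parameters
#'
#' @param iq_value USD per IQ point, base-year 2008 USD (default 18832; the
#'   low-end alternative used in uncertainty analysis is 8013).
#' @param iq_value_low Low-end USD per IQ point (default 8013).
#' @param vsl Value of statistical life, base-year 2005 USD (default 6.3e6).
#' @param vsl_range Plausible VSL range in USD (default 1e6 to 1e7).
#' @param discount_rate Annual discount rate (default 0.03).
#' @param horizon_year Year to which losses are realised (default 2050).
#' @param deflator_2008,deflator_2005 Multiplicative factors converting
#'   base-year USD to report-year (2020) USD. Defaults of 1.0 are documented
#'   placeholders: the source inflation series is not specified, so unit
#'   values are carried at their printed base-year magnitudes.
#' @param convention `"future_value"` (default) compounds each year's loss
#'   forward to the horizon; `"present_value"` discounts to 2010 instead.
#' @return A list of class `"valuation_params"`.
#' @export
valuation_params <- function(iq_value = 18832, iq_value_low = 8013,
                             vsl = 6.3e6, vsl_range = c(1e6, 1e7),
                             discount_rate = 0.03, horizon_year = 2050,
                             deflator_2008 = 1.0, deflator_2005 = 1.0,
                             convention = c("future_value", "present_value")) {
  convention <- match.arg(convention)
  pos <- c(iq_value = iq_value, iq_value_low = iq_value_low, vsl = vsl,
           deflator_2008 = deflator_2008, deflator_2005 = deflator_2005)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    abort("Monetary values and deflators must be finite and > 0.")
  }
  if (!is.finite(discount_rate) || discount_rate < 0 || discount_rate >= 1) {
    abort("`discount_rate` must lie in [0, 1).")
  }
  if (length(vsl_range) != 2 || any(vsl_range <= 0) || vsl_range[1] > vsl_range[2]) {
    abort("`vsl_range` must be an increasing pair of positive values.")
  }
  structure(
    list(iq_value = iq_value, iq_value_low = iq_value_low, vsl = vsl,
         vsl_range = vsl_range, discount_rate = discount_rate,
         horizon_year = horizon_year, deflator_2008 = deflator_2008,
         deflator_2005 = deflator_2005, convention = convention),
    class = "valuation_params"
  )
}

# GDP benefit-transfer ratio for a country-year, with hard error when absent
gdp_ratio <- function(econ, country, year) {
  sel <- econ$country == country & econ$year == year
  if (!any(sel)) {
    abort(sprintf("No GDP record for %s in %d.", country, year))
  }
  i <- which(sel)[1]
  econ$gdp_pc_ppp[i] / econ$us_gdp_pc_ppp[i]
}

#' Monetary loss from IQ decrements
#'
#' `points * iq_value * deflator(2008 -> report year) * gdp_ratio`, where
#' `gdp_ratio` is the country's PPP-adjusted per-capita GDP over the US
#' value in the same year.
#'
#' @param points Total IQ points lost per year.
#' @param econ A validated economics table (see [economics_table()]).
#' @param country,year Country and year of the loss.
#' @param params A [valuation_params()] object.
#' @return Loss in USD.
#' @export
iq_monetary_loss <- function(points, econ, country, year,
                             params = valuation_params()) {
  if (any(points < 0)) abort("`points` must be >= 0.")
  points * params$iq_value * params$deflator_2008 * gdp_ratio(econ, country, year)
}

#' Monetary loss from fatal heart attacks (VSL approach)
#'
#' @param deaths Attributable deaths per year.
#' @inheritParams iq_monetary_loss
#' @return Loss in USD.
#' @export
fha_monetary_loss <- function(deaths, econ, country, year,
                              params = valuation_params()) {
  if (any(deaths < 0)) abort("`deaths` must be >= 0.")
  deaths * params$vsl * params$deflator_2005 * gdp_ratio(econ, country, year)
}

#' Accumulate a series of annual losses to the horizon year
#'
#' Under the default future-value convention each year's loss is compounded
#' forward: `sum_y L_y * (1 + rate)^(horizon - y)`. Under
#' `"present_value"`, losses are instead discounted back to 2010.
#'
#' @param losses Data frame with columns `year` and `loss` (USD), or a
#'   numeric vector named by year. Years beyond the horizon are rejected.
#' @param rate Annual discount rate (default 0.03).
#' @param horizon Horizon year (default 2050).
#' @param convention `"future_value"` (default) or `"present_value"`.
#' @return Accumulated loss in USD.
#' @export
#' @examples
#' discount_to_horizon(data.frame(year = c(2049, 2050), loss = c(1, 1)))
discount_to_horizon <- function(losses, rate = 0.03, horizon = 2050,
                                convention = c("future_value", "present_value")) {
  convention <- match.arg(convention)
  if (is.numeric(losses) && !is.null(names(losses))) {
    losses <- data.frame(year = as.numeric(names(losses)), loss = unname(losses))
  }
  if (!all(c("year", "loss") %in% names(losses))) {
    abort("`losses` needs columns `year` and `loss`.")
  }
  if (any(losses$year > horizon)) {
    abort(sprintf("Loss year(s) beyond the %d horizon.", horizon))
  }
  if (any(losses$loss < 0)) abort("Losses must be >= 0.")
  base <- if (convention == "future_value") horizon else 2010
  sum(losses$loss * (1 + rate)^(base - losses$year))
}
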