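# Dose-response models linking daily dietary MeHg intake (ug/person/day) to
# fetal IQ decrements, fatal heart attacks, and blood/hair biomarkers.
#
# The one-compartment pharmacokinetic chain is intake -> blood (beta) ->
# hair (lambda) -> effect (gamma for IQ, phi for FHA). The estimated daily
# intake per body weight (EDI) always enters multiplied by body weight, so
# the product EDI x BW is simply the daily intake in ug/day and the body
# weight cancels out of every health endpoint.

#' Dose-response and pharmacokinetic parameters
#'
#' @param beta Intake-to-blood coefficient, ug/L blood per ug/day intake
#'   (default 0.6).
#' @param lambda Blood-to-hair coefficient, ug/g hair per ug/L blood
#'   (default 0.2).
#' @param gamma IQ decrement per unit hair Hg, IQ points per ug/g
#'   (default 0.3).
#' @param phi Fatal-heart-attack log-linear coefficient, per ug/g hair
#'   (default 0.066).
#' @param omega Probability of causality for the FHA association, in \[0, 1\]
#'   (default 0.33).
#' @param bw Average adult female body weight in kg (default 60). Retained
#'   only for reporting per-kg intake; it cancels out of all endpoints.
#' @return A list of class `"dr_params"`.
#' @export
dose_response_params <- function(beta = 0.6, lambda = 0.2, gamma = 0.3,
                                 phi = 0.066, omega = 0.33, bw = 60) {
  vals <- c(beta = beta, lambda = lambda, gamma = gamma, phi = phi,
            omega = omega, bw = bw)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("All dose-response parameters must be finite and >= 0.")
  }
  if (omega > 1) abort("`omega` is a probability and must lie in [0, 1].")
  structure(as.list(vals), class = "dr_params")
}

#' @export
print.dr_params <- function(x, ...) {
  cat("MeHg dose-response parameters:\n")
  cat(sprintf("  beta   %.3g ug/L per ug/day   lambda %.3g ug/g per ug/L\n",
              x$beta, x$lambda))
  cat(sprintf("  gamma  %.3g IQ pts per ug/g   phi    %.3g per ug/g\n",
              x$gamma, x$phi))
  cat(sprintf("  omega  %.3g                   bw     %.3g kg\n", x$omega, x$bw))
  invisible(x)
}

check_intake <- function(intake) {
  if (any(!is.finite(intake)) || any(intake < 0)) {
    abort("Daily MeHg intake must be finite and >= 0 (ug/person/day).")
  }
  invisible(intake)
}

#' Per-fetus IQ decrement from maternal dietary MeHg intake
#'
#' Linear no-threshold model: the IQ loss per fetus is
#' `gamma * lambda * beta * intake`, with intake in ug/person/day. The body
#' weight cancels and does not enter.
#'
#' @param intake Daily MeHg intake, ug/person/day (vectorised).
#' @param params A [dose_response_params()] object.
#' @return IQ points lost per fetus.
#' @export
#' @examples
#' per_fetus_iq(33) # highest national seafood exposure on record
per_fetus_iq <- function(intake, params = dose_response_params()) {
  check_intake(intake)
  params$gamma * params$lambda * params$beta * intake
}

#' Total annual IQ loss for a birth cohort
#'
#' @param per_fetus Per-fetus IQ decrement (points).
#' @param births Number of newborns per year (or a demographics table row
#'   set from which births are taken).
#' @return Total IQ points lost per year.
#' @export
total_iq_loss <- function(per_fetus, births) {
  if (is.data.frame(births)) births <- births$births[1]
  if (any(per_fetus < 0) || any(births < 0)) {
    abort("`per_fetus` and `births` must be >= 0.")
  }
  per_fetus * births
}

# attributable FHA death fraction at a given intake; saturates at omega
fha_attributable_fraction <- function(intake, params) {
  params$omega * (1 - exp(-params$phi * params$lambda * params$beta * intake))
}

#' Fatal heart attack deaths attributable to MeHg exposure
#'
#' Log-linear model in hair Hg, evaluated per gender and summed:
#' `sum_g POP_g * Cf_g * omega * (1 - exp(-phi*lambda*beta*intake))`, where
#' `Cf_g` is the age-adjusted baseline incidence of fatal heart attack. The
#' response is zero at zero intake, increases monotonically, and saturates
#' at `omega` times the baseline deaths.
#'
#' @param intake Daily MeHg intake, ug/person/day (single value applied to
#'   both genders).
#' @param demo Demographics rows for one country-year (male and female), or
#'   any data frame with `gender`, `population`, `fha_incidence`.
#' @param params A [dose_response_params()] object.
#' @return Attributable deaths per year.
#' @export
#' @examples
#' demo <- data.frame(country = "AAA", year = 2010,
#'                    gender = c("male", "female"),
#'                    population = c(1e6, 0), fha_incidence = c(0.002, 0),
#'                    births = 0)
#' fha_deaths(10, demo)
fha_deaths <- function(intake, demo, params = dose_response_params()) {
  check_intake(intake)
  if (length(intake) != 1) abort("`intake` must be a single value per country-year.")
  if (any(demo$fha_incidence < 0)) {
    abort("Baseline FHA incidence must be >= 0.")
  }
  sum(demo$population * demo$fha_incidence) * fha_attributable_fraction(intake, params)
}

#' Blood and hair Hg biomarkers implied by dietary intake
#'
#' One-compartment steady-state estimates: `blood = beta * intake` (ug/L)
#' and `hair = lambda * blood` (ug/g).
#'
#' @inheritParams per_fetus_iq
#' @return Tibble with columns `intake`, `blood`, `hair`.
#' @export
#' @examples
#' biomarkers(16) # Greenland-like seafood intake
biomarkers <- function(intake, params = dose_response_params()) {
  check_intake(intake)
  blood <- params$beta * intake
  tibble::tibble(intake = intake, blood = blood, hair = params$lambda * blood)
}

#' Compare predicted and measured biomarker concentrations across countries
#'
#' @param predicted,measured Paired numeric vectors (same countries, same
#'   order), at least 3 pairs.
#' @return A list with `r` (Pearson correlation), `n`, and per-set `mean`
#'   and `sd` (`predicted_mean`, `predicted_sd`, `measured_mean`,
#'   `measured_sd`).
#' @export
evaluate_biomarkers <- function(predicted, measured) {
  if (length(predicted) != length(measured)) {
    abort("`predicted` and `measured` must be paired (equal length).")
  }
  ok <- is.finite(predicted) & is.finite(measured)
  predicted <- predicted[ok]
  measured <- measured[ok]
  if (length(predicted) < 3) {
    abort("Need at least 3 paired countries to evaluate biomarkers.")
  }
  list(
    r = cor(predicted, measured),
    n = length(predicted),
    predicted_mean = mean(predicted),
    predicted_sd = sd(predicted),
    measured_mean = mean(measured),
    measured_sd = sd(measured)
  )
}
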