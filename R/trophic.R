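#' Trophic-level bins used for fish and aquatic-animal concentrations
#'
#' Fish and aquatic-animal methylmercury concentrations biomagnify strongly
#' with trophic position, spanning roughly an order of magnitude from
#' herbivorous species to apex predators. Concentration data are therefore
#' grouped into four trophic-level bins before geometric means are taken:
#' 2--2.5, 2.5--3.5, 3.5--4.5 and 4.5--5. The bins are contiguous,
#' non-overlapping and cover the full range \[2, 5\].
#'
#' @return A tibble with columns `bin` (label), `lower` and `upper`
#'   (trophic levels). Bins are left-closed; the last bin is closed on both
#'   sides so that trophic level 5 is representable.
#' @export
#' @examples
#' trophic_bins()
trophic_bins <- function() {
  tibble::tibble(
    bin   = c("2-2.5", "2.5-3.5", "3.5-4.5", "4.5-5"),
    lower = c(2, 2.5, 3.5, 4.5),
    upper = c(2.5, 3.5, 4.5, 5)
  )
}

#' Assign trophic levels to bins
#'
#' @param trophic_level Numeric vector of trophic levels; all values must lie
#'   in \[2, 5\].
#' @return Character vector of bin labels (see [trophic_bins()]).
#' @export
#' @examples
#' assign_trophic_bin(c(2.1, 3.0, 4.9))
assign_trophic_bin <- function(trophic_level) {
  if (!is.numeric(trophic_level)) {
    abort("`trophic_level` must be numeric.")
  }
  bad <- which(is.na(trophic_level) | trophic_level < 2 | trophic_level > 5)
  if (length(bad) > 0) {
    abort(sprintf(
      "Trophic level outside [2, 5] at position(s) %s (value(s): %s).",
      paste(head(bad, 5), collapse = ", "),
      paste(format(trophic_level[head(bad, 5)]), collapse = ", ")
    ))
  }
  bins <- trophic_bins()
  idx <- findInterval(trophic_level, bins$lower)
  bins$bin[idx]
}

#' Bin concentration samples and compute per-bin geometric means
#'
#' Literature concentration measurements arrive as (trophic level,
#' concentration) pairs. This groups them into the four trophic-level bins and
#' summarises each non-empty bin by the geometric mean, the geometric standard
#' deviation, and the sample count. Empty bins are absent from the result
#' rather than reported as zero.
#'
#' @param samples A data frame with numeric columns `trophic_level` (in
#'   \[2, 5\]) and `concentration` (ug MeHg per g food, strictly positive).
#' @return A tibble with columns `bin`, `geo_mean`, `geo_sd` (NA when n = 1)
#'   and `n`, one row per non-empty bin in bin order.
#' @export
#' @examples
#' bin_concentrations(data.frame(
#'   trophic_level = c(3.0, 3.2, 4.0),
#'   concentration = c(1, 100, 0.3)
#' ))
bin_concentrations <- function(samples) {
  samples <- tibble::as_tibble(samples)
  if (!all(c("trophic_level", "concentration") %in% names(samples))) {
    abort("`samples` needs columns `trophic_level` and `concentration`.")
  }
  bad <- which(!is.finite(samples$concentration) | samples$concentration <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "Non-positive concentration in sample(s) %s (trophic level %s, value %s); concentrations must be > 0.",
      paste(head(bad, 5), collapse = ", "),
      paste(format(samples$trophic_level[head(bad, 5)]), collapse = ", "),
      paste(format(samples$concentration[head(bad, 5)]), collapse = ", ")
    ))
  }
  samples$bin <- assign_trophic_bin(samples$trophic_level)
  out <- samples |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      geo_mean = exp(mean(log(.data$concentration))),
      geo_sd = if (dplyr::n() > 1) exp(sd(log(.data$concentration))) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
  out[match(trophic_bins()$bin, out$bin, nomatch = 0L), , drop = FALSE]
}

#' Allocate a country's fish consumption across trophic-level bins
#'
#' When a detailed consumption inventory by trophic bin is available, the
#' total is split proportionally by the supplied fractions. Otherwise the
#' marine trophic index (MTI) of the country's catch is used as a fallback:
#' by default all consumption is assigned to the single bin containing the
#' MTI; `spread = "triangular"` instead places half the consumption in that
#' bin and a quarter in each adjacent bin (renormalised at the edges).
#'
#' @param total_intake Total fish intake, g/person/day (>= 0).
#' @param fractions Optional numeric vector of length 4 (bin order of
#'   [trophic_bins()]), non-negative, summing to 1 within 1e-9.
#' @param mti Optional marine trophic index in \[2, 5\]; used when
#'   `fractions` is missing.
#' @param spread Fallback policy for `mti`: `"single"` (default) or
#'   `"triangular"`.
#' @return Named numeric vector of per-bin intakes (g/day) summing to
#'   `total_intake`.
#' @export
#' @examples
#' allocate_fish_consumption(20, fractions = c(0.1, 0.6, 0.25, 0.05))
#' allocate_fish_consumption(10, mti = 3.0)
allocate_fish_consumption <- function(total_intake, fractions = NULL, mti = NULL,
                                      spread = c("single", "triangular")) {
  spread <- match.arg(spread)
  if (!is.numeric(total_intake) || length(total_intake) != 1 || !is.finite(total_intake) ||
      total_intake < 0) {
    abort("`total_intake` must be a single non-negative number (g/day).")
  }
  bins <- trophic_bins()
  if (!is.null(fractions)) {
    if (length(fractions) != nrow(bins) || any(!is.finite(fractions)) || any(fractions < 0)) {
      abort("`fractions` must be 4 non-negative numbers (one per trophic bin).")
    }
    if (abs(sum(fractions) - 1) > 1e-9) {
      abort(sprintf("`fractions` must sum to 1 (got %.12f).", sum(fractions)))
    }
    w <- fractions
  } else if (!is.null(mti)) {
    if (!is.numeric(mti) || length(mti) != 1 || is.na(mti) || mti < 2 || mti > 5) {
      abort("`mti` must be a single trophic level in [2, 5].")
    }
    i <- match(assign_trophic_bin(mti), bins$bin)
    w <- numeric(nrow(bins))
    if (spread == "single") {
      w[i] <- 1
    } else {
      w[i] <- 0.5
      if (i > 1) w[i - 1] <- 0.25
      if (i < nrow(bins)) w[i + 1] <- 0.25
      w <- w / sum(w)
    }
  } else {
    abort("Supply either `fractions` or `mti`.")
  }
  setNames(total_intake * w, bins$bin)
}
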