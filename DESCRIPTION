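Package: mehgrisk
Title: Dietary Methylmercury Exposure, Health Effects, and Economic Valuation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Country-resolved assessment of dietary methylmercury (MeHg)
    exposure and its health and economic consequences. Aggregates per-capita
    exposure from seafood, freshwater fish, and rice consumption using
    trophic-level-binned concentration data; projects future exposure under
    emission scenarios by proportional scaling against environmental proxies
    (atmospheric deposition, soil mercury, plankton MeHg); converts intake to
    fetal IQ decrements and fatal-heart-attack deaths through epidemiological
    dose-response models; monetizes both endpoints with GDP-scaled unit values
    and discounting; and propagates input uncertainty by Monte Carlo. Includes
    a calibrated synthetic-world generator so the full pipeline runs and is
    testable without external food, demographic, or emission databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
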