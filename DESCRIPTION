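Package: tetrao
Title: Climate, Phenology and Breeding Success of Boreal Forest Grouse
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for long-term climate-phenology-demography
    analyses of boreal forest grouse (capercaillie and black grouse).
    Derives phenological onset dates (snow-free ground, frost-free nights,
    growing-degree-day thresholds) from daily weather series, anchors
    species-specific breeding-season temperature windows on lek mating
    dates, aggregates August pointing-dog brood surveys into demographic
    indices (breeding success, brood frequency, brood size), and runs the
    accompanying statistical battery: ordinary-least-squares trends with
    AR(1)/AR(2) generalized-least-squares comparison, total-change
    conversion, normalized and log-ratio interspecific comparisons,
    climate-window regressions, partial regressions controlling for small
    rodents and red fox, and a hatch-date mismatch analysis with
    polynomial model selection. A synthetic-data generator emulates the
    study system so the full pipeline is exercisable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr
Config/testthat/edition: 3
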