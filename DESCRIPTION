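Package: homeqaly
Title: Health Impact Modelling of Home Energy-Efficiency Retrofits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale health impact assessment pipeline for housing
    energy-efficiency programmes. Generates a seeded synthetic dwelling
    stock with linked occupants and mortality schedules, applies retrofit
    and ventilation scenarios, computes changes in five indoor exposures
    (standardised internal temperature, secondhand tobacco smoke, PM2.5 of
    indoor and outdoor origin, radon and mould risk) with a single-zone
    steady-state mass-balance model, and converts exposure changes into
    quality-adjusted life year (QALY) impacts over a 50-year follow-up via
    sex-specific annual life tables with disease-specific lag functions,
    morbidity models for common mental disorders and childhood asthma,
    Monte Carlo credible intervals, and structural sensitivity analyses
    for high-risk group size and indoor-particle toxicity.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    truncnorm,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
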