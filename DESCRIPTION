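Package: ahpfisc
Title: Lifetime Fiscal Projection of Acute Hepatic Porphyria with Recurrent Attacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A public-economic (government-perspective) lifetime projection model
    for acute hepatic porphyria (AHP) with recurrent attacks, parameterised for
    Belgium. Projects mortality-adjusted, discounted annual streams of gross
    earnings, direct (tax-wedge) and indirect (VAT) tax revenue, disability and
    retirement-pension transfers, and health costs for clinical scenarios of an
    individual diagnosed at age 30, and compares them with a general-population
    comparator. Includes micro-costing of hospitalised attack episodes, a
    Gompertz-Makeham synthetic-country generator with calibration to published
    lifetime totals, one-way sensitivity analysis with tornado ranking, and tidy
    accessors and ggplot2 graphics for every result type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
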