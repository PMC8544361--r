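Package: agecost
Title: Projected Utilisation and Cost of Dental Services for Older Australians
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A deterministic demand-and-expenditure model for dental services
    used by Australians aged 65 and over. Annual dental visits are projected
    per population stratum from a national per-person visit rate, decomposed
    into nine clinical service areas via a service mix (mean services per
    visit), priced from a fee schedule derived from itemised private-practice
    fees, and aggregated by jurisdiction, socioeconomic-disadvantage (IRSD)
    decile and remoteness class. Includes a synthetic small-area census
    generator that emulates SA1-like population units, a fee calibration
    routine that back-derives implied per-visit fees from published cost
    tables, reporting views in the style of national cost tables, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
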