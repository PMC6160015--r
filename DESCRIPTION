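Package: pricehealth
Title: Health and Economic Modelling of Food Price Discount Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-based cost-effectiveness modelling of food and beverage
    price discounts in remote Indigenous Australian communities. Converts
    store-sales dietary changes into price elasticities, population BMI and
    sodium shifts, potential-impact-fraction driven proportional multi-state
    lifetable estimates of disability-adjusted life years, itemised
    intervention costs with CPI deflation and treatment cost-offsets, and
    incremental cost-effectiveness ratios with Monte Carlo uncertainty
    analysis on the cost-effectiveness plane.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
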