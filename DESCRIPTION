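Package: agroprofit
Title: Spatially Explicit Ex Ante Assessment of Fertilizer Profitability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spatial framework for evaluating the agronomic and economic
    returns to mineral fertilizer use by smallholder maize farmers. The package
    generates fully synthetic study landscapes (terrain, soils, rainfall
    histories, road networks, market towns, farm surveys and household adoption
    panels) with known ground truth, estimates least-cost travel times to
    market over a friction surface, predicts local market and farm-gate prices
    for maize and nitrogen under transport-cost arbitrage, fits a regression
    forest of maize yield response to nitrogen, optimises per-pixel nitrogen
    rates for yield or net revenue, propagates interannual rainfall variability
    into distributions of returns, and validates predicted profitability
    against fertilizer adoption with a Mundlak correlated-random-effects linear
    probability model and cluster-robust inference.
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
    igraph,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
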