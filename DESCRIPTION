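Package: copcplan
Title: Population-Based Planning and Cost-Benefit Modelling for
    Community-Oriented Primary Care
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A deterministic planning pipeline for ICT-enabled
    community-oriented primary care (COPC) in rural districts: synthesis
    of small-area populations with skewed household incomes, nearest-facility
    catchment assignment with proximal/distal/remote service classes,
    income-quintile risk-adjusted service demand, community health worker
    (CHW) workforce sizing, line-item annual costing, lives and life-years
    saved with effectiveness bounds, cost-effectiveness (cost per life-year
    saved, threshold effectiveness) and cost-benefit analysis
    (human-capital discounted earnings, health-system savings,
    benefit-to-cost ratio). Ships a reference scenario for the Waterberg
    district of Limpopo, South Africa.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
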