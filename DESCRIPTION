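Package: ccusair
Title: Health and Cost-Benefit Assessment of Carbon Capture Pathways for Aviation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An airport-level assessment chain for carbon capture, utilization
    and storage (CCUS) adoption in aviation. Generates seeded synthetic worlds
    (airport registries, exposed populations, baseline mortality, business-as-usual
    emission inventories), applies proportional adoption ramps for four capture
    pathways (DAC-CCS, DAC-CCU, PSC-CCS, PSC-CCU), converts annual emissions into
    long-term mean ground-level concentrations with a sector-averaged Gaussian
    plume, estimates attributable mortality stratified by age, sex and disease
    with GEMM and log-linear exposure-response functions, and evaluates pathway
    costs against carbon-price revenues to produce net-benefit bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    purrr,
    rlang,
    stats,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
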