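Package: oralforce
Title: Needs-Based Oral Health Workforce Planning Simulation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation toolkit for needs-based planning of the oral health
    workforce. Projects the stock of registered dentists year by year from an
    initial register, flow assumptions and the graduate training pipeline, and
    converts stock to full-time-equivalent (FTE) provider supply via
    participation and activity rates. Estimates per-capita annual dental visit
    rates by sex, age band and oral health status from Eurobarometer-style
    survey microdata, converts population need into total service minutes and
    FTE provider requirement, and compares supply with requirement over a
    planning horizon under named scenario overrides. Includes a synthetic-data
    generator with known ground truth for survey microdata, population
    projections and register snapshot pairs, plus a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    jsonlite,
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
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
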