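Package: reefbleach
Title: Coral Bleaching Survey Indices, Thermal Stress Metrics, and Survey Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quadrat-based coral bleaching surveys: a validated
    long-format data model for colony health records scored in six ordered
    categories (Healthy through Dead); the Bleaching Response Index (BRI,
    a weighted average of category percentages on a 0-100 scale) at genus
    and site level; the community Bleaching Susceptibility Index (BSI);
    bleaching prevalence, colony density and period-to-period mortality
    change; degree heating weeks (DHW) from daily sea-surface-temperature
    series via a monthly climatology and maximum monthly mean baseline;
    matched-sample comparisons of bleached and dead relative abundance
    between survey periods; and a synthetic survey and SST generator with
    negative-binomial quadrat counts and multinomial category assignment
    for end-to-end testing of the pipeline.
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
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
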