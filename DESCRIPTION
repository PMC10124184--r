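Package: stereofec
Title: Stereological Fecundity and Size-at-Maturity Analysis for Bivalves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation toolkit for the reproductive biology of
    venerid clams. Generates synthetic three-dimensional gonads populated with
    spheroidal oocytes, cuts them into virtual serial histological sections,
    and reconstructs gonad volume (Cavalieri estimator), class-wise oocyte
    numbers (profile counts with Abercrombie correction), volume occupancy and
    partial fecundity from the section data. Also fits logistic size-at-maturity
    ogives (TL50), cohort-level regressions of gonad volume and fecundity on
    shell length with prediction intervals, occupancy ANOVA/ANCOVA with Tukey
    contrasts, minimum conservation reference size (MCRS) egg-output scenarios,
    and descriptive phenology summaries of environmental series and monthly
    maturity-stage composition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tools,
    car,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
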