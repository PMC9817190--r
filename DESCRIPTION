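Package: quadpop
Title: Quadrat-Survey Community Structure and Static Life-Table Demography for Shrub Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing woody-plant population demography and community
    structure from fixed-area quadrat surveys, built around the space-for-time
    substitution of basal-diameter size classes for age classes. Reads and
    validates stem and herb census tables, computes per-species layer summaries
    and relative importance values (RIV), builds static life tables (survivors,
    deaths, stage-specific mortality, life expectancy, killing power), fits
    exponential and power survivorship curves by log-scale least squares with
    Deevey-type classification, derives the cumulative survival, mortality,
    mortality-density and hazard-rate functions, and forecasts age-class
    abundances with moving averages. A seeded synthetic-survey generator
    emulates inverted-J shrub communities so every pipeline stage is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
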