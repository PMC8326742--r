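Package: agewell
Title: Gender-Stratified Life Tables, Health Expectancies and Active Ageing Indices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for gender-stratified quality-of-life analysis of older
    adults: abridged life tables from age-grouped population and death counts,
    Sullivan-method disability-free and morbidity-free life expectancies with
    Chiang-style variances, scoring of the GDS-15 depression scale, the 6-item
    De Jong Gierveld loneliness scale and the WHOQOL-BREF, Active Ageing
    Indices on the EU (weighted-indicator) and WHO (HDI-normalised) scales,
    the associated group-comparison statistics, and a synthetic-cohort
    generator that emulates the structure of the census and survey microdata
    such analyses are usually run on.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
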