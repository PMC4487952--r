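Package: landcc
Title: Land Carrying Capacity Assessment with Ecological Footprint and
    Index System Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assesses regional land carrying capacity (LCC) from multi-year
    city panels using two complementary frameworks.  Ecological footprint
    analysis converts consumption and land-area panels into per-capita
    footprint and biocapacity ledgers over six biologically productive land
    categories, with ecological surplus/deficit series and trend
    decomposition.  The index system method normalizes a year-by-indicator
    socioeconomic panel with indicator polarity, derives dispersion-based
    (mean-squared-error) weights, aggregates to criterion-layer and
    integrated scores, grades them on a five-level standard, and projects
    indicators linearly to future years.  A seeded synthetic-city generator
    with known ground truth makes both pipelines fully testable offline,
    and a reporting layer renders the comparative assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
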