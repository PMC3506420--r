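Package: swrisk
Title: Source Water Hazard Screening and Buffer-Zone Risk Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated risk-assessment pipeline for drinking-water source
    watersheds. Computes quantitative hazard quotients (the ratio of an
    exposure concentration to a water-quality standard) from censored
    monitoring summaries against Class A surface-water and drinking-water
    standard sets, and a qualitative source-proximity-extent (S x P x E) risk
    matrix over riparian buffer zones derived from a grid distance-to-stream
    transform, with four-band risk classification and ranked per-sub-watershed
    reports. Includes a synthetic generator for monthly monitoring series with
    non-detects and for watershed land-use grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
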