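Package: mobqol7d
Title: Valuation and Scoring for the MobQoL-7D Mobility-Related Quality of Life Instrument
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for preference-based valuation of the MobQoL-7D, a
    seven-dimension, four-level descriptive system for mobility-related
    quality of life. Constructs anchored personal utility functions from
    OPUF-style survey responses (dimension swing weights, within-dimension
    level ratings on a visual analogue scale, and a dead-anchoring task),
    aggregates them into group value sets with bootstrap confidence
    intervals, scores all 16,384 MobQoL-7D health states (including with
    the published general-population and mobility-impaired value sets),
    computes QALYs and population norms, and compares value sets between
    samples. A seeded synthetic-respondent generator reproduces the
    statistical structure of the survey so the full pipeline is testable
    without respondent-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
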