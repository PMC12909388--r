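Package: physgrowth
Title: Growth-Plate Kinetics from Pulsed Fluorochrome Labeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for fluorochrome double-label histomorphometry
    of vertebral growth plates (physes) under mechanical growth modulation.
    Traces operator-annotated label fronts, computes pixel-wise growth-distance
    fields along the axis of longitudinal growth, derives regional growth rates
    (anterior quarter, middle half, posterior quarter) and the percent growth
    modulation statistic, measures physeal zone thickness, epiphyseal
    ossification fraction, nucleus pulposus centroid position and signed
    sagittal Cobb angles, and runs the cohort-level statistics (Grubbs outlier
    test, one-tailed pairwise t tests with Bonferroni correction, one-way
    ANOVA, post hoc power and sample-size analysis). Includes a synthetic-data
    generator that renders two-channel label-band images over curved fronts
    with a known growth field and simulates multi-animal cohorts with a
    prescribed level-wise modulation structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
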