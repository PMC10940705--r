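Package: calscreen
Title: Kinetic Calcium-Flux Plate Screening and Agonist-Selective Hit Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for ultra-high-throughput kinetic calcium
    fluorescence screens of platelet agonist signaling. Extracts seven curve
    characteristics (baseline, maximal increase, rise slope, peak, post-peak
    and late-phase slopes, area under the curve) from per-well fluorescence
    traces, filters duplicate plates by a difference-index reproducibility
    statistic, normalizes to in-plate agonist controls, calls active compounds
    by per-plate Z-scores, runs the agonist-specificity hit-selection cascade
    with stage-count reporting, confirms hits by four-parameter logistic
    IC50 fitting, and compares compound effect profiles by correlation,
    Euclidean distance, k-means and principal components. Includes a seeded
    synthetic 1536-well plate-screen generator with planted compound effects
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
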