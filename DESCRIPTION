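Package: stimChar
Title: Physical Characterization, Nutrition Metadata and Normative Ratings
    for Visual Food Stimuli
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the physical appearance of experimental stimulus
    photographs on white background (color-channel contribution, object size,
    brightness, within-object contrast, radially averaged spatial-frequency
    power, and Canny-edge complexity), manages per-image nutrition metadata
    (caloric density, macronutrients, portion totals, high/low caloric-density
    median split), aggregates participant visual-analog-scale ratings into
    per-image norms with subgroup stratification and paired category
    contrasts, and selects condition subsets of images matched on arbitrary
    features. Ships deterministic generators for synthetic stimulus images
    with analytic ground truth and for simulated rating surveys, so every
    metric and statistic is testable without the original photographs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jpeg
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
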