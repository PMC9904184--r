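Package: fermkin
Title: Forage Fermentation Kinetics and Mobile-Bag Digestion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies forage carbohydrate digestion in horses from two
    complementary assays. For the in vitro gas production technique, converts
    vented headspace pressure traces to cumulative gas volumes via the ideal
    gas law, fits the monophasic sigmoidal gas-production model by nonlinear
    least squares, and derives the asymptotic gas production, half-time,
    shape constant, time of maximum digestion rate, and dry matter
    disappearance. For the mobile nylon-bag technique, computes transit time,
    caecal and total recovery rates, washing loss, per-nutrient precaecal
    disappearance, recovery-interval pooling, and a common-slope (parallel
    lines) regression of dry matter disappearance on residence time. Includes
    seeded synthetic-data generators emulating both experiments so every
    stage of the pipeline is testable without animal data, plus CSV schema
    validation and report helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
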