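Package: rareconc
Title: Rare Event Concentration Coefficient for Spatial Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to measure how strongly rare events (road accidents,
    crimes, and other low-frequency point events) concentrate in space.
    Point records are discretised into per-unit counts by hexagonal
    tessellation or fixed-length road segmentation; per-unit counts are
    modelled as a finite Poisson mixture fitted by non-parametric maximum
    likelihood (vertex exchange method plus EM refinement); concentration
    is summarised with the Rare Event Concentration Coefficient (the Gini
    coefficient of the fitted rate distribution), Lorenz curves, the naive
    count-based Gini for comparison, exposure-normalised risk ratios, a
    Clark-Evans nearest-neighbour test of complete spatial randomness, and
    Monte Carlo confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
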