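Package: antnest
Title: Age-Dependent Density Regulation of Ant Nest Excavation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling and analysing nest excavation dynamics in ant
    colonies. Implements an age-dependent density-regulation digging model in
    which each ant excavates toward an age-specific target area per ant, forward
    simulation of whole-colony excavation over arbitrary demographic timelines
    (including artificial nest collapse and per-ant attribution of dug area),
    synthetic generators for colony-maturation and fixed-demographics
    experiments, estimation procedures (target-area line, basal digging rate,
    area-population scaling, logistic population fits, lagged cross-correlation
    of digging and population growth, collapse-recovery fractions), and an image
    pipeline that registers nest photographs, measures excavated area, and
    segments binary nest masks into tunnels, wide tunnels and chambers with
    gravity-referenced orientation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    jsonlite,
    png,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
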