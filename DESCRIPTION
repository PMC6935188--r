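Package: fasdcea
Title: Cost-Effectiveness Modelling of Screening Tools for Fetal Alcohol
    Spectrum Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic modelling of screening strategies for fetal
    alcohol spectrum disorder (FASD) in a pediatric cohort. Pools published
    diagnostic accuracies of meconium fatty acid ethyl ester testing and the
    Neurobehavioral Screening Tool with DerSimonian-Laird random effects,
    feeds them into a decision tree plus Markov cohort model tracking
    discounted costs and years lived with an accurate FASD diagnosis to age
    18, and computes incremental cost-effectiveness ratios with one-way
    (tornado) and probabilistic sensitivity analyses, including
    cost-effectiveness acceptability curves and cost-effectiveness plane
    data. A per-individual microsimulation provides an independent check of
    the cohort engine, and a synthetic life-table generator stands in for
    national life tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
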