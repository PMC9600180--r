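Package: rarestab
Title: Dynamics and Stability of Rare and Abundant Soil Bacterial Taxa
    Under Environmental Disturbance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for disturbance-recovery mesocosm experiments
    on soil bacterial communities. Classifies OTUs into abundance categories
    (always/conditionally abundant, moderate, always/conditionally rare),
    tracks category-level abundance flux, computes rarefaction, Shannon
    diversity and log response ratios per subcommunity, implements
    Bray-Curtis dissimilarity, principal-coordinate analysis, PERMANOVA and
    SIMPER from their definitions, provides a reduced negative-binomial Wald
    differential-abundance procedure with Benjamini-Hochberg correction and
    responsive-OTU filtering, and fits an analytic impulse-response
    ("stability landscape") model of diversity recovery in a Bayesian
    framework with an affine-invariant ensemble sampler. A synthetic
    community generator reproduces the statistical structure of the mesocosm
    design so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    biomformat
Config/testthat/edition: 3
RoxygenNote: 7.3.3
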