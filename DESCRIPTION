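Package: cyclevag
Title: Longitudinal Dynamics of the Vaginal Microbiota over the Menstrual Cycle
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing short-term longitudinal 16S profiles of the
    vaginal microbiota sampled at four menstrual-cycle phases (follicular,
    ovulatory, early luteal, late luteal). Provides a synthetic cohort
    generator with known ground truth (logistic-normal compositions, cyclic
    hormone trajectories, configurable visit and hormone effects), sample-level
    quality control and rarefaction, centered log-ratio transforms with a
    stepwise covariate-residualisation ladder, alpha/beta diversity and
    ordination with per-visit covariate screening, two beta-diversity
    comparison procedures (per-phase and self-versus-random resampling),
    random-intercept models of taxon trajectories with permutation empirical
    p-values, intraclass correlation decomposition, hormone-taxa association
    models, and nearest-centroid community state type (CST) classification
    with longitudinal transition statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    lme4,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    sandwich,
    withr,
    optparse,
    ape,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Microbiome, Metagenomics, Software, TimeCourse
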