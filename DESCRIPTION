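Package: thermoplast
Title: Thermal Plasticity Analysis: Hierarchical TPC Inference, Permutation
    Statistics, Co-Expression Modules and Regulatory Windows
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing thermal acclimation experiments in
    ectotherms. Fits Kamykowski-type thermal performance curves to sprint
    speed data anchored by critical thermal limits via a hierarchical
    Bayesian model with logit-bounded, non-centred parameterisation, and
    derives posterior maximum performance (Pmax) and optimal temperature
    (Topt) by two-stage grid search. Provides permutation inference for the
    accompanying behavioural designs (Freedman-Lane ANCOVA, split-plot
    repeated-measures ANOVA with simple-effect post hocs, Holm and
    Benjamini-Hochberg adjustment, rank tests), a signed biweight
    midcorrelation co-expression network workflow (soft-power selection,
    topological-overlap modules, eigengenes, kME, module-trait association,
    hub genes, bootstrap module stability, Fisher overlap tests), and
    strand-aware gene-proximal and promoter window construction with
    differential-peak and footprint-score filtering. Seeded synthetic-data
    generators with recorded ground truth support end-to-end testing
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
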