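Package: ldscreen
Title: Quantitative High-Throughput Analysis of Lipid-Storage Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for quantitative high-throughput (qHTS)
    phenotypic screens of cellular lipid storage. Raw plate signals are
    normalized to lipid-droplet content per cell, per-compound titrations are
    fitted with a four-parameter logistic (Hill) model, and hits are called
    and triaged by qHTS curve classes (complete sigmoid, partial curve,
    single-point activity, inactive) with cytotoxicity counter-screen flags
    and structural-series support. Companion stages cover the downstream
    computations of such a campaign: an intergenic-background expression
    cutoff, replicate quality control, differential-expression calls,
    Z-score k-means expression signatures, gene-set enrichment, one-way
    ANOVA with Bonferroni post-hoc tests for whole-animal triglyceride data,
    a pharmacogenetic epistasis decision rule, and enzyme-inhibition IC50
    estimation. Seeded synthetic-data generators with attached ground truth
    make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
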