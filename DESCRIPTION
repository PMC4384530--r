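Package: episcan
Title: Directional Epistasis Mapping from Multi-Phenotype Combinatorial
    RNAi Screens
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis stack for template-query combinatorial RNAi screens
    with image-based multi-parametric phenotypes. Provides a
    variance-stabilising transformation, replicate- and reagent-level
    quality-control filters, step-wise selection of a non-redundant
    phenotype subset, estimation of single-gene main effects and pairwise
    interaction scores (pi-scores) by two-way median polish under a
    multiplicative model, empirical-Bayes moderated testing with
    Benjamini-Hochberg adjustment, an interaction-profile correlation
    network, and a caller for signed, directed epistatic relations that
    fits each gene pair's multivariate interaction vector against the two
    single-gene effect vectors. A synthetic screen generator with known
    ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    limma,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
biocViews: Software, CellBasedAssays, QualityControl, Network,
    GraphAndNetwork, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'direction.R'
    'episcan-package.R'
    'featureSelection.R'
    'io.R'
    'network.R'
    'pipeline.R'
    'qc.R'
    'scoring.R'
    'simulate.R'
    'transform.R'
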