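Package: ithquant
Title: Quantification of Intra-Tumor Heterogeneity from Digital Pathology Label Maps
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies spatial intra-tumor heterogeneity (ITH) in breast
    cancer whole-slide analyses from deep-learning-derived label maps.
    Builds registered patch grids over tissue / nuclei / digital-grade label
    maps, computes normalized co-occurrence matrices and Haralick-style
    texture statistics plus colocalization over a 162-feature catalogue,
    assembles family heterogeneity scores and a Cox-beta-weighted overall
    ITH score dichotomized at a minimum-p-value survival cut-point, and
    provides the accompanying survival and association statistics. Includes
    a synthetic cohort generator with a controllable true heterogeneity
    level for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    jsonlite,
    yaml,
    png,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'catalogue.R'
    'cooccurrence.R'
    'features.R'
    'io.R'
    'ithquant-package.R'
    'survival.R'
    'scores.R'
    'utils.R'
    'synthetic.R'
    'pipeline.R'
    'preprocess.R'
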