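Package: mitopla
Title: Automated In Situ Proximity Ligation Imaging and AP-MS Interactome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An automated analysis pipeline for in situ proximity ligation
    assay (is-PLA) microscopy and affinity-purification mass-spectrometry
    (AP-MS) interactome screens of mitotic cells. Provides maximum-intensity
    projection of multi-field z-stack acquisitions, background subtraction,
    threshold segmentation with size and circularity filters, automatic
    classification of interphase nuclei versus mitotic figures, per-cell PLA
    sum-intensity quantification within segmentation masks, and nonparametric
    comparison of control versus importazole-treated conditions. A companion
    module filters MaxQuant-style protein-group tables by identification
    confidence, tests bait-versus-IgG enrichment with down-shifted-normal
    imputation, and cross-tabulates hits against mitotic phenotype
    annotations. A synthetic-scene simulator generates ground-truthed
    acquisitions and fixture tables so the whole pipeline can be exercised
    and benchmarked without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
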