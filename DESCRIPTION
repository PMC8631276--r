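Package: dmrlink
Title: Integrative Methylome-Transcriptome Linking of Differentially
    Methylated Promoters and Enhancers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for integrative analysis of paired tumor/adjacent
    whole-genome bisulfite methylomes and transcriptomes. Implements an
    age-stratified combined Baumgartner-Weiss-Schindler (BWS) rank test
    with permutation calibration for differentially methylated locus
    (DML) detection, distance-based merging of DML into differentially
    methylated regions (DMRs), genomic-location and chromatin-state
    annotation of DMRs, enhancer-RNA based discovery of active
    intergenic enhancers, correlation-based linking of promoter- and
    enhancer-like DMRs to differentially expressed genes (including
    methylation-eRNA-gene triple correlation), high-confidence
    screening, independent-cohort replication accounting with raw and
    platform-adjusted rates, and survival/stage association of
    candidate epigenetic drivers. A synthetic-cohort generator with a
    planted-truth manifest supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    stats,
    utils,
    survival,
    IRanges,
    S4Vectors,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
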