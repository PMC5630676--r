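Package: cfhmc
Title: Cell-Free 5-Hydroxymethylcytosine Enrichment Sequencing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of cell-free DNA 5-hydroxymethylcytosine
    (5hmC) enrichment sequencing (hMe-Seal-style pull-down versus input
    libraries): spike-in enrichment quality control, Poisson local-background
    calling of 5hmC-enriched regions (hMRs), gene-body/promoter/window FPKM
    quantification and metagene profiles, differential hydroxymethylation
    statistics (Welch t, empirical-Bayes moderated t, Benjamini-Hochberg),
    copy-number estimation from cfDNA with GC-LOESS correction, and a
    leave-one-out cancer-type classification stack (EDDA Gaussian mixture,
    random forest, Cohen's kappa, linear-discriminant disease score).
    Includes a fully synthetic cohort generator with planted ground truth so
    every stage can be validated against known effects.
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
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust
Config/testthat/edition: 3
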