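Package: adcmine
Title: Antibody-Drug Conjugate Target Discovery from Tissue-Proteomic
    Expression Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers and prioritizes candidate antibody-drug conjugate
    (ADC) targets from Human Protein Atlas style immunohistochemistry
    tables. Implements a multi-stage screening funnel over membrane
    protein-coding genes (protein-level evidence, exclusion of genes highly
    expressed in 13 critical normal tissues, a cohort-level quasi H-score
    with a 150-point threshold, and a surfaceome intersection), a
    three-flag validation layer (RNA consistency, literature conformity,
    membranous staining), tissue-microarray H-score statistics (one-sample
    t-tests against cohort scores, Pearson score-FPKM correlation), a
    seeded synthetic-data generator with planted ground truth, and heat-map
    reporting with tabular sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    stats,
    tools,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
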