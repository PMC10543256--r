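Package: synshift
Title: Shift-Ability Screening of Perturbation Transcriptomes for
    Chemo-Immunotherapy Synergy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives anti-PD-1 resistance (R) and sensitivity (S) gene
    signatures from paired pre-/on-treatment tumor transcriptomes, scores
    compound- and shRNA-induced expression profiles with the shift-ability
    statistic (the difference between the weighted Kolmogorov-Smirnov
    enrichment scores of the S and R signatures), prioritizes drug targets by
    compound/knockdown concordance and immune association in pan-cancer
    cohorts, and clusters resistance-shifting compounds into mechanism groups
    by consensus expression-change signatures. Includes a from-scratch
    preranked GSEA and ssGSEA engine, synthetic-data generators that emulate
    paired immunotherapy cohorts, level-5-style perturbation compendia and
    pan-cancer survival cohorts, and a config-driven end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC,
    optparse
Config/testthat/edition: 3
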