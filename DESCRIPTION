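Package: pleioscan
Title: Reverse Engineering Laboratory Evolution of Postponed Senescence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for evolve-and-resequence studies of postponed
    reproductive senescence in Drosophila. Detects genomic intervals of
    near-fixed allele-frequency divergence between replicate selected and
    control populations, filters candidate genes by divergence P-value,
    expression and RNAi-stock availability, calls RNAi-screen effects on
    lifespan and reproduction with classical expected-mean-squares ANOVA
    models (including nested random vial effects and Tukey-Kramer
    comparisons), and classifies genes into antagonistic-pleiotropy
    categories. Includes a seeded synthetic-data generator emulating the
    study design so the whole chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    vcfR,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
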