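Package: maqcna
Title: Copy-Number Aberration Calling from Multiplex Amplicon Quantification Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Dosage-quotient analysis of multiplex amplicon fragment data for
    targeted copy-number aberration calling, developed around the neuroblastoma
    prognostic regions (1p, MYCN/2p, 3p, 11q, 17q). Normalizes fluorescence peak
    areas against reference amplicons and control samples, applies rule-based
    scoring of segmental and whole-chromosome aberrations and MYCN amplification
    under either the MAQ or the MLPA threshold set, evaluates calls against a
    gold standard (sensitivity, specificity, predictive values, ROC AUC, pooled
    error rates, Bland-Altman repeatability), and ships a synthetic fragment-data
    simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
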