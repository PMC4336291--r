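Package: chispas
Title: Quality Control for Sequence-Phenotype Assignments in
    Saturation-Mutagenesis Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects incorrect sequence-phenotype assignments (ISPAs) in
    selection-based saturation-mutagenesis screens. Reads amplicon pools
    from two phenotype classes, extracts and validates degenerate-codon
    (SNS) variable regions, and tests every variant observed in both
    phenotypes against an experimentally calibrated error rate under a
    binomial Z-score model (Agresti-Coull interval) and a conjugate
    Beta-binomial model with highest-posterior-density intervals. Also
    quantifies the downstream impact of ISPAs on critical-residue
    predictors via perturbation-based reliability analysis
    (sensitivity/specificity/MCC envelopes, reliable region, competence),
    and ships a synthetic-screen generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
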