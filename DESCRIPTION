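Package: sphingoquant
Title: Targeted Plasma Sphingolipidomics: Quantification, QC and Case-Control Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for targeted (dynamic-MRM) plasma sphingolipidomics
    of ceramides and glycosphingolipids. Parses sphingolipid shorthand nomenclature
    into head group, sphingoid base and N-acyl chain; annotates vendor peak lists
    against a transition library by precursor/product m/z and retention time;
    quantifies species against class-matched internal standards; applies pooled-QC
    anchored drift correction and CV/dilution-linearity admission filters;
    computes case-control statistics (Welch t tests with Benjamini-Hochberg
    control, subclass/base/acyl aggregation, lipid ratios with adjusted odds
    ratios, ROC models, severity regressions, clinical summary tables); performs
    lipid set enrichment analysis with a permutation null; and pools per-study
    gene-expression effects by DerSimonian-Laird random-effects meta-analysis.
    A synthetic-data generator emulates the full acquisition (panel, cohort,
    injection runs with drift and QC structure, dilution series, multi-study
    effect sets) with ground-truth records for validation.
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
    metafor,
    jsonlite
Config/testthat/edition: 3
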