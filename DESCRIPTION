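Package: igfam
Title: Familial Immunoglobulin Biomarker Analysis in High-Risk Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for serum immunoglobulin biomarkers in
    high-risk chronic lymphocytic leukemia (CLL) pedigrees. Derives
    polyclonal (kappa+lambda sums) and monoclonal (kappa/lambda ratio)
    variables from eight-analyte free light chain (FLC) and heavy/light
    chain (HLC) serum panels, classifies abnormal phenotypes against
    diagnostic and control-derived 95 percent reference ranges, fits
    propensity-score-adjusted linear and Firth bias-reduced logistic
    models for relative-versus-control comparisons, and compares cancer
    configurations between pedigrees harboring abnormal phenotypes and
    "normal" pedigrees using unique first- to third-degree bloodline
    relatives and Fisher exact conditional maximum-likelihood odds
    ratios. Includes a seeded generator of multi-generational pedigrees,
    serum panels, and cancer diagnoses so the whole pipeline is testable
    without access to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
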