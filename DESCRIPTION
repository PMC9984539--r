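Package: plasmapanel
Title: Multi-Omic Plasma Biomarker Panel Construction for Cavernous Angioma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building weighted-combination diagnostic biomarkers
    from plasma multi-omic measurements (metabolite peak intensities, protein
    concentrations, miRNA qPCR Cq values), as used in cavernous angioma (CA)
    and symptomatic-hemorrhage (CASH) biomarker studies. Implements
    partial-least-squares discriminant analysis with permutation significance
    and Benjamini-Hochberg FDR for differential-feature discovery,
    propensity-score nearest-neighbor case-control matching,
    metabolite-protein Pearson correlation screening, delta-Cq normalization
    with endogenous-control stability ranking, ridge-penalized logistic
    biomarker models with leave-one-out and stratified k-fold
    cross-validation, Youden-index and AIC model selection,
    correlation-based feature selection, fixed weighted-combination model
    evaluation, file-based pathway enrichment with minimum-Bayes-factor
    screening, and a synthetic multi-omic cohort generator so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
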