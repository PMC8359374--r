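Package: episignr
Title: Blood DNA Methylation Episignature Discovery and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and applying peripheral-blood DNA methylation
    episignatures from Infinium EPIC-style beta-value matrices. Implements
    probe and array quality filtering, age/sex matched control selection,
    M-value transformation, reference-based blood cell deconvolution,
    empirical-Bayes moderated-t differential methylation with a three-stage
    probe-selection funnel (effect-size/p-value ranking, per-probe ROC,
    correlation pruning), an SVM-based methylation variant pathogenicity
    (MVP) classifier with Platt-calibrated probabilities, leave-one-out
    cross-validation, differentially methylated region calling with Fisher
    and Stouffer p-value combination, and genomic feature / chromatin-state
    enrichment scoring. Includes a synthetic EPIC-like cohort generator with
    known planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    methods,
    e1071,
    jsonlite,
    pracma,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
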