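Package: editsig
Title: Blood A-to-I RNA Editing Biomarker Signatures for Psychiatric Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for blood A-to-I RNA editing biomarkers over a
    targeted eight-gene amplicon panel (CAMK1D, GAB2, IFNAR1, KCNJ15, LYN,
    MDM2, PDE8A, PRKCB): editing quantification from aligned reads or
    nucleotide-count tables (site, isoform and motif biomarkers), adaptive
    differential testing with Benjamini-Hochberg false discovery control,
    correlation pruning and shadow-feature (Boruta-style) selection, per-gene
    Target Editing Index via the Su-Liu AUC-maximizing linear combination with
    Box-Cox transformation, per-comparison multivariate-ROC virtual markers
    with sensitivity/specificity/PPV/NPV reporting, covariate-adjusted
    multiclass random-forest classification with multi-indicator feature
    importance, and Monte-Carlo tabular augmentation with fidelity validation.
    Includes a seeded synthetic-cohort generator emulating a four-group
    psychiatric case-control study so the whole pipeline is testable without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    caret,
    optparse,
    pROC,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
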