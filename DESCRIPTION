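Package: rppadyn
Title: Dynamic Phospho-Proteomic Drug-Response Analysis for Cancer
    Cell-Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing drug-perturbation time-course proteomics
    in cancer cell-line panels, from reverse-phase protein array (RPPA)
    spot quantification through to survival stratification of patient
    cohorts. Aggregates replicate spots with robust outlier exclusion,
    normalises against control MIX spots, assembles per-antibody protein
    expression time courses, classifies their kinetics (early,
    intermediate, late, no response) by K-means clustering, estimates
    GI50 and dose-response AUC from viability tables, associates copy
    number loss with drug sensitivity via exact tests, ranks proteins by
    Pearson correlation with sensitivity or with anchor phosphoproteins,
    and stratifies survival cohorts (Kaplan-Meier, log-rank, Cox hazard
    ratios, subgroup and per-gene hazard screens). A synthetic-data
    module generates every input with recorded ground truth so the whole
    pipeline is testable without access to restricted data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
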