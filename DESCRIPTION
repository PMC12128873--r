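Package: aneuscope
Title: Aneuploidy Burden Scoring, Screen Epistasis, and Burden-Stratified
    Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes net-gain aneuploidy burden (gain minus loss megabases
    or gene counts) from copy-number segment tables with tumor purity
    correction, from gene-level copy-number matrices, or inferred from
    expression data by reference-normalised moving-average smoothing.
    Profiles paired aneuploid/diploid CRISPR knockout screens: guide-level
    log fold changes, a chromosomal-location bias correction for
    copy-number-altered arms, permutation-based gene-level essentiality
    tests, epistasis profiles, and pre-ranked gene-set enrichment with the
    weighted Kolmogorov-Smirnov running sum. Associates feature matrices
    (metabolite abundances, gene-effect scores) with burden by linear
    regression, computes extracellular-flux bioenergetics metrics, and
    stratifies survival cohorts by burden class and chemotherapy exposure
    using hand-rolled Kaplan-Meier and Efron-tie Cox estimators. A
    synthetic-data module generates all inputs with planted truth so the
    full pipeline is testable without external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    fgsea,
    withr
Config/testthat/edition: 3
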