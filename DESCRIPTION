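Package: nanopotency
Title: Dose-Response Potency Ranking and Pathway Enrichment for Nanoform
    Cytotoxicity Screens
Version: 0.1.0
Authors@R:
    person("NanoPotency", "Maintainers", email = "maintainers@nanopotency.example",
           role = c("aut", "cre"))
Description: Tools for ranking the in vitro cytotoxic potency of nanoforms
    (size, coating, crystal-phase variants of one nanomaterial) from plate-based
    dose-response data, and for downstream mechanistic analysis of secreted
    and cellular proteomes. Raw assay signals are normalized to dose-zero
    controls to give fold effects, fitted with the power-law model
    FE = (dose + 1)^beta by through-origin log-log regression, averaged across
    LDH, ATP and resazurin (CTB) endpoints into a consensus potency beta_avg,
    and densely ranked. A correlation screen relates consensus potency to
    physicochemical descriptors and oxidative-stress/cytokine markers, with
    rank-transform factorial ANOVA and Holm-Sidak adjustment. A from-scratch
    preranked gene set enrichment analysis (running-sum enrichment score,
    permutation NES, sign-stratified FDR), NES-matrix hierarchical clustering
    and hypergeometric over-representation cover the proteomic stage. A
    seed-deterministic synthetic-data generator emulates every input so the
    whole pipeline is testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
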