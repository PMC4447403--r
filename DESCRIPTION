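Package: emstate
Title: Epithelial-Mesenchymal Signature Derivation, Survival Association and
    Single-Cell State-Space Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for linking epithelial (E) and mesenchymal (M) gene
    expression programs to stemness and patient outcome. Derives E, M and
    combined EM gene signatures from clone-labelled expression matrices by
    moderated differential expression and effect-size ranking; scores
    patients with a signature, classifies breast cancer subtypes from marker
    probes, and estimates Kaplan-Meier curves, logrank statistics and Cox
    hazard ratios for best-cutoff dichotomized scores; assesses signature
    specificity with random-gene-set permutation nulls and gene-subsampling;
    processes single-cell qPCR Cq plates (background estimation from
    no-template controls, linear transformation, per-gene max
    normalization) into an E-M state space; and tests group separation with
    the cross-match test based on an exact minimum-weight perfect matching
    together with its closed-form permutation null. A synthetic-data module
    generates clone matrices, survival cohorts and Cq plates with known
    ground truth for calibration and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    utils
LinkingTo: Rcpp
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
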