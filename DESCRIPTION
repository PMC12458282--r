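Package: immunoscape
Title: Cross-Disease Immune Feature Meta-Analysis and Module Discovery
Version: 0.1.0
Authors@R: person("immunoscape", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Integrates multi-study case-control transcriptomic collections
    with random-effects meta-analysis (Hedges' g, DerSimonian-Laird),
    derives higher-order immune features (cell-type proportions by
    non-negative least-squares deconvolution, single-sample gene-set
    enrichment scores for pathways, transcription-factor regulons and
    miRNA targets, and cytokine panel expression), assembles cross-disease
    feature landscapes, discovers co-regulated immune modules by
    correlation clustering, and validates modules with size-matched
    permutation nulls, per-study ROC/AUC enrichment, treatment-response
    prediction and severity correlation. Ships a synthetic multi-study
    generator with planted effects, between-study heterogeneity and
    cell-mixture structure so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
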