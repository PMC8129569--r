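Package: sigclone
Title: Transcriptomic Signatures and Immunoglobulin Isoform Clonality for
    MYD88-Driven Lymphoplasmacytic Lymphoma Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two analyses used in mouse models of MYD88-driven
    lymphoplasmacytic lymphoma. The transcriptomic arm selects
    differentially expressed genes with a moderated t-statistic, aggregates
    k-means gene clusters under a standardized chi-square stopping rule,
    extracts a sign-coherent mouse/human ortholog signature, and classifies
    samples as Waldenstrom macroglobulinemia (WM) versus non-WM with a
    linear-predictor-score (LPS) Bayesian classifier. The repertoire arm
    merges 5'RACE amplicon read pairs, demultiplexes by barcode and
    isoform-specific primer, builds immunoglobulin heavy-chain clonotype
    tables, reports top-clone frequencies per membrane or secreted isoform
    library, matches dominant clones across isoforms, and compares groups
    with an exact Wilcoxon rank-sum test. A synthetic-data module generates
    expression cohorts and repertoire libraries with known planted
    structure so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
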