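Package: cernet
Title: Competing-Endogenous-RNA Network Discovery with Module Detection
    and Biomarker Diagnostics
Version: 0.1.0
Authors@R:
    person("cernet", "maintainers", email = "maintainers@cernet.invalid",
           role = c("aut", "cre"))
Description: Assembles circRNA-miRNA-mRNA competing-endogenous-RNA (ceRNA)
    networks from multi-layer differential expression and target-prediction
    tables. Provides moderated and Welch two-sample differential expression
    on log2 expression matrices, multi-database target-support filtering and
    Venn-style co-RNA derivation, exhaustive sponge-triplet assembly with an
    optional expression-direction consistency filter, a reimplementation of
    the MCODE molecular-complex detection algorithm with degree-based hub
    ranking, hypergeometric over-representation analysis of GMT gene-set
    collections, single-feature ROC/AUC biomarker evaluation with exact
    small-sample significance, a synthetic-data generator with planted
    sponge axes for end-to-end validation, and a configuration-driven
    pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
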