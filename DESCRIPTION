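Package: spongenet
Title: miRNA Sponge (ceRNA) Network Inference from Small-RNA and Transcript Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for discovering miRNA-centred
    competing endogenous RNA (ceRNA) networks from small-RNA sequencing reads
    and multi-class expression matrices. Implements staged small-RNA read
    filtering with full per-category accounting, clean-tag collapsing with a
    read-frequency cutoff, priority-ordered tag annotation, transcripts-per-
    million normalisation, a negative-binomial exact test for two-group
    differential screening, canonical seed-match miRNA target prediction,
    Spearman anti-correlation and Pearson co-expression screens, ceRNA triplet
    and network assembly with Cytoscape-compatible export, and hypergeometric
    over-representation analysis. A synthetic-data generator with planted
    ground truth (differential miRNAs and sponge triplets) supports recovery
    and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
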