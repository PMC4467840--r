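Package: cisnat
Title: Topology, Conservation and Feature Cross-Referencing of cis-Natural
    Antisense Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native pipeline for analysing cis-natural antisense
    transcripts (cis-NATs) of protein-coding genes. Classifies cis-NATs into
    five overlap topologies, extracts the parts of their footprints that do
    not overlap protein-coding exons (NOLPs), builds a non-redundant NOLP
    set, scores NOLP sequence conservation across a multi-species whole
    genome alignment with a branch-length-scale likelihood-ratio test under
    a neutral reversible substitution model, calls conservation of antisense
    expression in a sister genome via seed-and-extend transcript mapping and
    bidirectional-best-hit orthologs, compares observed feature counts with a
    matched near-gene resampling null, and cross-references NOLPs with
    ChIP-seq peaks, small interfering RNAs, transposons and protein homology
    using exact hypergeometric tests. A synthetic-data generator with known
    ground truth emulates every input the pipeline consumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    Rcpp,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
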