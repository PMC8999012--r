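Package: proxscreen
Title: Network-Based Drug-Disease Proximity Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generalized network-based drug-disease proximity on a
    protein-protein interactome. Summarizes shortest-path distances between a
    drug's target module and a disease's gene module under five metrics
    (minimum, maximum, mean, median, mode), assesses significance with a
    degree-preserving randomization null model, screens candidate drugs at a
    p-value cutoff, and provides an in-silico validation stage with paired
    differential-expression disease signatures and a Kolmogorov-Smirnov
    connectivity enrichment score with a binary counteraction call. Includes a
    synthetic-data module (scale-free interactomes, planted proximal modules,
    paired expression with known differential genes, drug ranked lists) so the
    whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
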