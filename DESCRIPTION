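Package: pphnet
Title: Persistent Path Homology of Directed Gene Pathway Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Integrates gene expression data with directed pathway networks
    (e.g. KEGG) via persistent path homology. Pathway graphs are read from
    KGML files, edge lists or adjacency matrices; edges are weighted by the
    correlation distance 1 - |rho| between the expression profiles of their
    endpoint genes within one condition, defining a filtration from 0 to 1
    in steps of 0.01. Regular path homology in dimensions 0 and 1 is
    computed with exact finite-field linear algebra at every filtration
    step, yielding Betti curves, persistence barcodes and persistence
    landscapes. Landscapes are averaged, differenced between two conditions
    and compared with permutation tests on their sup-, 1- and 2-norms;
    per-pathway Kolmogorov-Smirnov statistics and Cohen's d on the Betti
    series, with label-permutation p-values and Benjamini-Hochberg
    correction across pathways, flag pathways whose directed topology
    differs between conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    igraph,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
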