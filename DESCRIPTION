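Package: epictrees
Title: Enhancer-Promoter Tree Models and In Silico Enhancer Perturbation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds graph-based enhancer-promoter "tree" models from
    cell-type-resolved chromatin loop (HiChIP-style BEDPE) and accessibility
    (ATAC) tables: consensus anchor/loop construction, breadth-first level
    assignment with redundant-edge pruning, enhancer forests and connectivity
    statistics, distance and nearest-promoter skipping analyses, a
    k-nearest-neighbour classifier that scores per-enhancer contributions to
    cell-type-specific gene expression by in silico node removal, and
    annotation of disease-associated variants with candidate enhancer-gene
    links. A seeded synthetic-data generator lets the whole pipeline run
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    class
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
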