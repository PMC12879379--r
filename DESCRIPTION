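Package: regulogic
Title: Regulatory Grammar of Cell-Type-Specific Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for dissecting the cis-regulatory logic of cell-type-specific
    gene expression. Ranks genes by expression specificity between a target and a
    background cell population, curates proximal and distal regulatory regions and
    links distal regions to genes through chromatin interactions, discovers novel
    DNA sequence motifs by permissive k-mer Hamming clustering, scans sequences
    with position weight matrices using exact score p-values, tests motifs and
    motif pairs for enrichment in gene-linked regulatory regions by Monte Carlo
    sampling, designs combinatorial oriented-motif reporter (STARR-seq) libraries
    on a screened synthetic background sequence, and scores reporter count tables
    for motif orientation, copy-number, position, pair and order effects. A
    synthetic-data module generates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
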