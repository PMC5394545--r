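Package: sahnet
Title: lncRNA-mRNA Co-Expression Network Analysis for Experimental
    Subarachnoid Haemorrhage RNA-Seq
Version: 0.1.0
Authors@R:
    person("sahnet", "maintainers", email = "sahnet@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a bulk RNA-seq analysis
    pipeline for early brain injury after experimental subarachnoid
    haemorrhage in mice: RPKM quantification with log10(RPKM+1)
    transformation and GC-stratified count normalization, two-group
    differential expression via the conditional binomial
    (random-sampling) test with Benjamini-Hochberg q-values, novel
    long non-coding RNA classification by length and open-reading-frame
    coding potential, and a bipartite lncRNA x mRNA co-expression
    network built from Pearson correlations assessed by exhaustive or
    Monte-Carlo permutation tests with Z-score standardization.
    Includes mapping/region QC summaries, hypergeometric gene-set
    over-representation with FDR, Cytoscape-compatible network export,
    and a seeded synthetic-data generator (negative-binomial counts
    with planted fold changes and planted correlated pairs) so that
    every stage is verifiable without raw sequencing reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
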