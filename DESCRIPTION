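Package: pauseScape
Title: RNA Polymerase II Pausing and Regulatory Chromatin Landscape Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies RNA polymerase II promoter-proximal pausing from
    binned ChIP-seq coverage tracks (pausing index with the standard
    promoter-window and gene-width exclusion rules), bins genes by expression
    (FPKM) and pausing strength, scores facultative versus constitutive
    heterochromatin from H3K27me3/H3K9me3 signal, stitches H3K27ac peaks into
    enhancers and calls super-enhancers with the rank-curve tangent cutoff,
    computes Fisher exact-test log-odds enrichment heatmaps over equal-sized
    gene bins, builds anchor-centered metagene profiles with outlier removal,
    and post-processes promoter-capture Hi-C interaction tables (replicate
    read filtering, distance cap, quantile normalization, per-gene interaction
    summaries and condition comparisons). A seeded synthetic-data generator
    produces toy genomes, coverage tracks, expression counts, peak sets and
    two-replicate contact tables with the statistical structure these analyses
    assume, and a pipeline driver runs all stages reproducibly from one
    configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
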