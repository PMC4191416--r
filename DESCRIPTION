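Package: spliceRetention
Title: Junction-Ratio and Intron-Retention Analysis for Paired RNA-seq
    Splicing Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies splicing defects between a wild-type and a mutant
    RNA-seq sample from splice-junction and intron-body read counts.
    Implements per-million normalization with zero-count and low-CPM
    junction filters, mutant/wild-type exon-exon junction ratios for
    dot-plot export, an intron-retention index (intron-body reads per kb
    per million mapped) with strict greater-than-2-fold missplicing
    classification, and standard-curve qPCR quantification with
    act1-normalized relative expression and ChIP enrichment. A seeded
    synthetic-data generator emulates a paired two-sample experiment
    (intron-containing gene fraction, unequal library sizes, heavy-tailed
    expression, Poisson count noise, an implanted set of misspliced
    introns) together with its ground truth, so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'annotation.R'
    'junctions-io.R'
    'analysis.R'
    'simulate.R'
    'qpcr.R'
    'pipeline.R'
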