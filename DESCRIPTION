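Package: pirliver
Title: piRNA and piRNA-Like Profiling from Small RNA-Seq of Liver Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end, reproducible pipeline for profiling
    PIWI-interacting RNAs (piRNAs) and novel piRNA-like loci from
    adapter-trimmed small RNA-seq reads, designed around the stepwise
    lesions of human hepatocarcinogenesis (cirrhotic nodule through
    progressed hepatocellular carcinoma). Collapses reads and classifies
    them against a known small non-coding RNA annotation, discovers
    unannotated piRNA-like loci with a k-mer discriminant and strand-aware
    interval merging, normalises to reads per million, calls rank-sum
    differential-expression signatures with fold-change and false
    discovery rate thresholds, computes 5'-U / position-10-A biogenesis
    bias statistics and positional composition, annotates genomic context
    (UTR/CDS/intron/intergenic), predicts piRNA-to-transcript target sites
    by a 20-nt guide with mismatches, and clusters samples by Ward linkage
    on Kendall correlation. Ships a fully seeded synthetic-data generator
    with recorded ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
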