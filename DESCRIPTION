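Package: sRNAstress
Title: Discovery and Stress-Response Profiling of Bacterial Small RNAs
    from RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-scale discovery and characterization of
    stress-responsive small RNAs (sRNAs) in bacteria from mapped RNA-seq
    data. Implements interoperonic-region (IOR) candidate calling with a
    read-count threshold, elimination of UTR bleed-through false
    positives, pairwise negative-binomial differential expression of
    sRNAs under graded metabolite stress against an unstressed control,
    expression-pattern clustering with percentile abundance ranking, and
    sequence-level characterization of candidates (Rho-independent
    terminator detection, rule-based Hfq-binding motif classification,
    and promoter PSSM scanning). Ships a synthetic-data generator that
    emulates a low-GC genome with planted operons, sRNAs and UTR-bleed
    decoys under a multi-condition, multi-time-point stress design, so
    the whole pipeline can be exercised and calibrated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    ape,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
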