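Package: ribostall
Title: Detection of Compound-Induced Ribosome Stalling from Ribosome Profiling Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting transcript-selective ribosome
    stalling from ribosome profiling (ribo-seq) and matched mRNA-seq data.
    Builds P-site-resolved read maps from transcriptome-coordinate
    alignments, computes metagene profiles, cumulative fractional read (CFR)
    curves and the D_max divergence statistic with expression-binned local
    Z-scores, performs downstream differential expression gated on the
    D_max position, center-of-density shift analysis, translational
    efficiency decomposition, and upstream ORF scanning. Includes a
    synthetic footprint generator with known stall ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    Rsamtools,
    DESeq2,
    S4Vectors,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
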