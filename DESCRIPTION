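Package: polycage
Title: Comparison of CAGE-Defined 5' Transcript Ends Between Translatome and Transcriptome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare transcript 5' isoforms between a
    polysome-associated (translatome) and a total-RNA (transcriptome) CAGE
    library. Implements tag clustering with a Poisson background model,
    feature-priority promoter annotation, four-way core-promoter shape
    classification (SP/DP/MP/BP), Kolmogorov-Smirnov testing of 5'-end
    distribution disparity between conditions, per-cluster and per-gene
    polysome-selection scores (fold-change score and differential-usage
    score), sequence-window characterization (GC content, AUG counts,
    TATA-box enrichment), and a synthetic two-condition CAGE data generator
    with a truth key for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
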