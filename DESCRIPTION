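Package: binscale
Title: Peak Quantification and Scaled Coverage Track Generation from BAM Files
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies sequencing peaks directly from coordinate-sorted BAM
    files against BED intervals, reporting raw read or fragment counts together
    with FPKM, TPM and library-size normalized scores based on effective
    library sizes obtained from a full filtered pass over the alignments.
    Generates scaled coverage tracks in bigWig or bedGraph format with
    genome-size, library-size or custom scaling, signal smoothing, two-sample
    log2 ratio and subtraction, and assay-specific presets: replication fork
    directionality (RFD) for OK-seq, replication timing log2 ratios,
    strand-resolved END-seq tracks, and splice-aware RNA-seq coverage with
    adaptive single-base resolution at sharp coverage changes. Includes a
    deterministic synthetic-data simulator and naive counting oracles so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    parallel,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Coverage, ChIPSeq, ATACSeq, RNASeq, Normalization, Sequencing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
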