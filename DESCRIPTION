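Package: bindcast
Title: Transcription-Factor Binding-Site Prediction from ATAC-seq with
    Dilated Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts transcription-factor binding sites (TFBS) genome-wide
    from chromatin accessibility (ATAC-seq or scATAC-seq pseudobulk) and DNA
    sequence. Implements Tn5 cut-site inference with strand-aware shifts,
    cut-site smoothing, depth normalization to reads-per-20-million and robust
    percentile min-max scaling, a dilated convolutional network operating on
    1,024 bp windows with 32 bp output resolution, peak-centric pan-cell
    training-example sampling with dice-coefficient model selection,
    genome-tiled prediction with score-to-precision/recall/F1 calibration, and
    precision-recall benchmarking at fixed-width genomic bins against ChIP-seq
    gold standards, including motif-scan and averaged-ChIP baselines. A
    deterministic synthetic-fixture generator with planted motifs supports
    end-to-end testing at toy scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    BiocGenerics,
    Rsamtools,
    GenomicAlignments,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
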