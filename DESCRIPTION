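Package: dismotif
Title: Discriminative Transcription Factor Binding Site Discovery from
    Expression Networks and Cross-Species Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative workflow for transcription factor binding site
    (TFBS) discovery. Infers TF target sets from expression data by rank-based
    mutual information with Data Processing Inequality pruning and bootstrap
    consensus networks; assembles and masks promoter sequence sets; identifies
    cross-species conserved promoter fragments by alignment-score coverage
    calibration and by deterministic sparse-pattern discovery across orthologs
    (robust to binding-site turnover); evaluates position weight matrices by
    classification relative-error rate with permutation nulls; and performs
    de novo discriminative motif discovery by enumerative search with local
    refinement. Includes a synthetic benchmark generator with planted
    regulatory structure so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
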