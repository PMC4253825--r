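Package: ampliCNA
Title: Copy Number Aberration Detection from Targeted Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects large copy number aberrations (CNAs) at gene resolution
    from ultra-deep targeted amplicon sequencing. Per-amplicon read counts are
    normalized for library size, GC content and amplicon length (LOESS),
    regressed on a principal-component baseline built from a small panel of
    diploid controls, segmented with a weighted circular binary segmentation,
    anchored to a mixture-based copy-neutral zero level, and validated with a
    fixed-variance test, a t-test and a purity/ploidy-aware detection-limit
    filter. Includes a synthetic-data generator with planted CNAs for
    end-to-end testing and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mclust,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    Rsamtools,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
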