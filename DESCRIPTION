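Package: faireCGI
Title: Chromatin Accessibility Analysis at H3K9me2 Nucleation Sites and CpG Islands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates FAIRE-seq chromatin accessibility with H3K9me2
    ChIP-seq peak annotation, CpG-island sequence composition and DNA
    methylation in hematopoietic stem and progenitor cells. Provides
    genomic-interval arithmetic and BED input/output, fragment coverage
    tracks (fixed-step wiggle and bedGraph), library-size normalised
    per-region fold changes between a G9a/GLP-inhibited condition and a
    control, a random-region resampling null, a Wilcoxon rank-sum test
    with an exact enumeration path, GC and CpG observed/expected
    composition scoring with CGI-like scanning, stratification of CGIs by
    promoter association, evolutionary class and methylation state, and a
    fully deterministic synthetic-data generator so the whole pipeline is
    testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
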