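Package: polybench
Title: Dosage-Aware Benchmarking of Polyploid Small-Variant Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing dosage-aware polyploid small-variant truth
    sets and for evaluating polyploid variant calls under two semantics:
    site-level detection and exact-genotype (allelic dosage) genotyping.
    Includes assembly-alignment-based confidence-region derivation, variant
    normalization and site harmonization, per-type hard filters and a
    reliable-region read filter, stratified precision/recall/F1 reports with
    dosage confusion matrices, and a deterministic synthetic-benchmark
    generator with bookkept error injection so the whole pipeline can be
    exercised without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
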