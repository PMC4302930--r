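Package: derepressr
Title: Identify Genes Derepressed by Loss of an H3K27me3 Methyltransferase
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrated RNA-seq/ChIP-seq pipeline for calling direct
    Polycomb (PRC2/H3K27me3) target genes that become derepressed when the
    methyltransferase is inactivated in a sorted cell population. Implements
    a magnitude-times-ratio differential-expression ranking score ("diffrat")
    with permutation-based empirical significance, a TSS-proximal ChIP-seq
    tag-density score with quantile-anchored 0-10 log scaling and a high/low
    mark call at 2/10, cross-referencing of the two into derepressed
    direct-target calls, Mendelian expected-fraction arithmetic and Fisher's
    exact test for rescue crosses, and a fully parameterised synthetic-data
    generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
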