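Package: cnvquartet
Title: Family-Aware Evaluation of CNV Call Sets in Twin Quartets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking copy-number variant (CNV) call sets using
    monozygotic twin quartets. Provides reciprocal-overlap interval matching,
    gap-threshold merging of fragmented calls, descriptive call-set statistics,
    Mendelian-consistency metrics (the inherited CNV rate), a familial
    relationship classification test (k-means on pairwise sharing rates scored
    by weighted F1), multi-caller agreement tables and pairwise
    union/intersection call sets, reciprocal-overlap threshold sweeps for
    breakpoint-resolution assessment, logistic-regression association of
    sequence features with call concordance, and a synthetic quartet simulator
    with configurable virtual-caller error profiles and full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
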