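Package: lfqpipe
Title: Label-Free Proteomics Differential Abundance with Cross-Stage
    Consistency Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for label-free quantitative (LFQ) proteomics of
    case-control designs: assembly of per-sample protein intensity reports
    into a master table, parts-per-million total-sum normalization, group-wise
    presence filtering, Mann-Whitney plus fold-change differential abundance
    with detection-aware handling of missing values, cross-stage consistency
    analysis with aging-effect correction, cross-tissue overlap tables,
    hypergeometric over-representation analysis with Benjamini-Hochberg
    correction, cross-study Spearman correlation, z-scaled Ward clustering
    for heatmaps, and a spike-in simulator that generates LFQ-like data with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
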