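Package: psipipe
Title: CRISPR Editing, Pseudouridylation and Isoform-Switch Analysis for
    scaRNA Disruption Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for CRISPR disruption studies of
    guide scaRNAs: indel-spectrum decomposition of Sanger chromatogram
    traces against shifted control templates with non-negative least
    squares (TIDE-style), relative expression by the delta-delta-Ct method
    with reference-gene normalization and a nested replicate test,
    site-specific pseudouridylation quantification from CMC reverse
    transcription stop RT-qPCR, transcript-level isoform-switch detection
    from count matrices via TMM normalization and per-transcript Poisson
    likelihood-ratio tests with Benjamini-Hochberg correction, and
    hypergeometric over-representation analysis with -ln(p) enrichment
    scores. Includes a seeded synthetic-data generator that plants ground
    truth for every stage, and a file-based pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    pracma,
    edgeR,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
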