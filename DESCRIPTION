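Package: replichip
Title: Replication Copy-Number Profiling and Internal-Standard ChIP-seq
    Normalization for Stalled-Fork Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing DNA replication and checkpoint-kinase
    ChIP-seq in budding yeast under replication stress. Implements
    copy-number profiling of hydroxyurea-arrested S-phase samples
    calibrated against dormant replicative regions, internal-standard
    normalization of ChIP-seq tracks using centromeric (Cse4) signal,
    origin-centered heatmaps and metaprofiles ordered by replication
    timing, and a synthetic-data generator that emulates stalled
    replication forks with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
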