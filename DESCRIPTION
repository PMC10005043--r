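Package: gfnet
Title: Robust Gene Functional Networks from Multi-Genotype Time-Course
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs gene functional networks (GFNs) from standardized
    time-course expression profiles measured in several independent
    genotypes. Gene pairs are connected only when their Pearson time-profile
    correlation passes a false-discovery-rate threshold, a minimum
    determination coefficient, and a regression-outlier screen, and - the
    defining requirement - when the relation is independently repeated in at
    least x of the a genotypes analysed. A binomial calculus predicts the
    chance rate of relations surviving the replication filter. Also provides
    transcription-factor candidate search for network genes, assembly of
    several GFNs into a meta-network linked by shared genes with
    pattern-wise average expression profiles, a synthetic-data generator
    emulating the multi-genotype fruit-development study design, and
    exporters (TSV, GraphML) with a thin command-line front end.
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
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
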