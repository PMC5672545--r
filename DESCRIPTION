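Package: crpod
Title: Concentration-Response Modeling and Point-of-Departure Estimation
    for Targeted RNA-Seq Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for high-throughput transcriptomic concentration-response
    analysis of targeted probe-sequencing (TempO-Seq-style) experiments: probe-level
    read counting from demultiplexed FASTQ files against a 50-mer probe manifest,
    count quality control (feature and sample filters, control PCA, D-statistic
    outlier detection) and median-of-ratios normalization, negative-binomial Wald
    tests for differential expression at the maximum tested concentration,
    permutation/moment-approximated trend tests and Wilcoxon statistical flags
    feeding a decision tree that selects gene-treatment pairs for curve fitting,
    and concentration-response model fitting (constant, gain-loss, three- and
    four-parameter Hill) with AIC selection and point-of-departure estimation at a
    one-standard-deviation baseline departure. Includes a synthetic-data generator
    emulating a shared-vehicle-control plate design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
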