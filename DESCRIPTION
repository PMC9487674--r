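Package: dsbench
Title: Benchmarking Differential-State Tests for Multi-Subject Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained framework for studying pseudoreplication bias in
    differential-state (DS) analysis of multi-subject single-cell RNA-seq data.
    Provides a hierarchical negative-binomial simulator with gene-level ground
    truth (including the DS categories DE/DP/DM/DB and the null categories
    EE/EP), pseudobulk aggregation with TMM and median-of-ratios normalization,
    simplified in-package analogues of the naive, latent-variable, mixed-model
    and pseudobulk test families, performance evaluation (AUROC, confusion
    metrics at an FDR cutoff, the average-overlap statistic), and the
    mock-comparison and reproducibility protocols used to assess false-discovery
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    MASS,
    lme4,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR,
    DESeq2,
    jsonlite,
    withr
Config/testthat/edition: 3
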