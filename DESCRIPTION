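Package: trimint
Title: Tri-Omics Integration by Correlated miRNA-CpG-mRNA Module Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A grouping-scoring-modeling pipeline that integrates miRNA
    expression, CpG methylation and mRNA expression measured on the same
    samples for a two-class phenotype. Correlated miRNA-CpG pairs are
    detected by exhaustive Pearson scanning, expanded into cross-omics gene
    groups, scored with a cross-validated random-forest classifier, and
    combined into cumulative top-k models. Group and feature significance
    is aggregated over many random train/test splits, yielding performance
    tables, significant-group and significant-feature summaries, rank
    co-occurrence matrices and a shared-gene similarity matrix. Includes a
    synthetic tri-omics data generator with planted latent-factor modules
    for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    ranger,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
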