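Package: dnbtip
Title: Dynamic Network Biomarker Detection of Transition Stages in Staged
    Transcriptome Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the tipping (transition) stage of a staged, replicated
    gene expression experiment with the dynamic network biomarker (DNB)
    framework: candidate genes with elevated replicate-level variability are
    selected per stage, clustered by absolute Pearson correlation, and each
    cluster is scored with the composite index CI = SD_in * |PCC_in| /
    |PCC_out|; the stage whose best cluster maximizes CI is reported as the
    tipping point and its members as the DNB gene set. Includes GeTMM
    (gene-length-corrected trimmed mean of M-values) normalization and
    low-expression filtering for count data, probe-to-gene collapsing,
    per-stage QC (coefficient of variation, PCA, sample clustering),
    overlay of DNB and differentially expressed gene sets on a transcription
    factor - target regulatory network with percentile-ranked expression and
    SD ratios, gene-set association by odds ratio and Fisher's exact test,
    GO enrichment by hypergeometric test with Benjamini-Hochberg control,
    and a synthetic-data generator with planted DNB modules for parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    edgeR,
    generics,
    ggplot2,
    igraph,
    jsonlite,
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
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
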