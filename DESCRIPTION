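Package: mscc
Title: Methyl-Sensitive Cut Counting Analysis of Differential DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for methyl-sensitive cut counting (MSCC)
    experiments: in-silico restriction digestion of a genome with a panel of
    methylation-sensitive enzymes, extraction and uniqueness screening of the
    27-nt CG tags the assay sequences, demultiplexing and one-mismatch tag
    mapping, per-site digestion-frequency normalization, Welch-test calling of
    differentially methylated sites with Benjamini-Hochberg FDR control,
    TSS-anchored metaprofiles with a permutation test of promoter enrichment,
    and downstream methylation-expression association (RPKM differential
    expression, odds ratios, hypergeometric gene-set enrichment). A synthetic
    data generator emulating the assay's measurement model makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    readr,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
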