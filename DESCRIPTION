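Package: mirisonet
Title: Integrative miRNA and Transcript-Isoform Co-Expression Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline linking plant microRNAs to transcript
    isoforms: complementarity-based target prediction with a position-dependent
    mispair penalty score, small-RNA cataloguing (length filtering, transposable
    element annotation, TPM quantification, differential expression), weighted
    isoform co-expression networks (topological overlap, module detection,
    eigengenes, kME hubs, module-trait correlation), miRNA-target expression
    correlation binning, isoform divergence statistics (genes with isoforms in
    different modules, hub-targeting enrichment, homolog categories), and
    Wallenius noncentral hypergeometric term enrichment. Includes a seeded
    synthetic-data generator with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    edgeR,
    Biostrings,
    rtracklayer,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
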