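Package: lncforge
Title: Identification and Characterisation of Long Non-Coding RNAs from
    Assembled Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for genome-wide long non-coding RNA
    (lncRNA) discovery from multi-assembler transcriptome assemblies.
    Implements consensus ("stringent") transcript selection across assemblers
    and tissues, intron-chain merging into a unique transcript set, a
    seven-stage identification cascade with class-code categorisation into
    intergenic (lincRNA), intronic (ilncRNA) and natural-antisense (lncNAT)
    transcripts, an ORF/Fickett/hexamer coding-potential scorer, Jensen-Shannon
    tissue-specificity scores, exact-binomial sex-bias tests with
    Benjamini-Hochberg correction and locus-level sex-bias ratios, miRNA
    precursor and seed-site (MRE) detection for ceRNA candidates, and weighted
    co-expression network analysis (soft-threshold adjacency, topological
    overlap, module eigengenes, kME, module-trait correlation, hypergeometric
    enrichment, hub selection). A fully deterministic synthetic-data generator
    with a machine-readable truth manifest makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
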