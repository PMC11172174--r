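Package: hybridpirna
Title: piRNA Pathway and Allele-Specific Expression Analysis for
    Interspecific Drosophila Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale reimplementation of the small-RNA and
    transcriptome analyses used to dissect female hybrid sterility in
    crosses between Drosophila melanogaster and Drosophila simulans.
    Provides a small-RNA read-processing cascade with explicit library
    depth bookkeeping for rpm normalization, an exact ungapped
    k-mismatch read mapper with all-hits, one-best and best-unique
    policies, 5'-to-5' overlap histograms and the ping-pong z10
    statistic (including a cross-set variant for AT-chX / vasa piRNA
    pairs), per-transposon-family piRNA quantification with
    silencing-potential classification and fold-reduction summaries, a
    transparent negative-binomial Wald test with Benjamini-Hochberg
    correction, ortholog resolution from tabular homology hits,
    allele-specific dosage-category classification in hybrids, and
    piRNA-cluster activity quantification by unique mapping to a merged
    two-genome reference. A seeded synthetic-data generator emulates
    diverged transcriptomes, transposon-derived piRNA libraries with
    planted ping-pong pairs, and negative-binomial RNA-seq counts with
    planted allele-dosage categories, so the whole pipeline runs and is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    stringi,
    utils,
    withr
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
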