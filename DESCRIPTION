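Package: drbstr
Title: Compression-Based Analysis of the MHC-DRB Intron-2 Microsatellite
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the short tandem repeat (STR) at the
    start of MHC-DRB intron 2 in New World monkeys. Partitions exon 2 +
    intron 2 amplicon alignments into named sectors and computes per-sector
    pairwise identity; detects imperfect (GA)-family microsatellite runs
    under explicit validity thresholds and decomposes the STR into initial,
    central and final sectors; derives alignment-free distances by tandem
    amplification followed by adaptive Lempel-Ziv (Unix compress .Z) coding;
    and builds hierarchical clusterings and neighbour-joining trees with
    bootstrap support, with concordance statistics between the groupings
    obtained from different gene sectors. Includes a seeded generator of
    lineage-structured synthetic amplicon panels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    mclust,
    yaml,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
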