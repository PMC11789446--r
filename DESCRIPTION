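Package: varcascade
Title: Germline Variant Prioritization Cascade with PPI Network Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, audited implementation of a germline variant
    prioritization pipeline for familial colorectal cancer exomes. Annotated
    variant calls are passed through a multi-gate filtering cascade (gnomAD
    allele-frequency filter, CADD deleteriousness filter, nine-tool consensus
    deleteriousness vote, conservation vote, loss-of-function evidence tiers
    with a last-exon exclusion), and the surviving genes are analyzed together
    with known predisposition genes by STRING-style channel-combined
    protein-protein interaction networks, Markov clustering, and hypergeometric
    gene-set enrichment with Benjamini-Hochberg false discovery control. A
    synthetic cohort and network generator with known ground truth makes every
    stage testable without controlled-access sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
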