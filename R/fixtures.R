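#' Packaged per-variant report fixture
#'
#' A 31-variant cohort table transcribing the package's reference
#' per-variant report of prioritized candidates from nine familial
#' colorectal cancer index cases: 20 missense, 6 stop-gain, 3 frameshift
#' and 2 canonical splice variants across three functional groups (DNA
#' repair / cell cycle; ECM / focal adhesion / TGF-beta signaling; the
#' candidate tumor suppressor DMBT1 hit in two families). Printed evidence
#' (CADD, vote score, constraint, MutPred2, SpliceAI/MMSplice) is carried
#' verbatim. Fields the cascade needs but the report does not print —
#' population frequencies, the per-tool categorical calls behind each vote
#' score, conservation scores, exon geometry — are synthetic values chosen
#' consistent with the variants having survived every gate; the per-tool
#' calls reproduce each printed vote score exactly.
#'
#' @return A `variant_table` with 31 rows.
#' @export
table2_variants <- function() {
  read_variant_table(system.file("extdata", "table2_variants.tsv",
                                 package = "varcascade"))
}

#' Packaged reference cluster table
#'
#' Transcription of the reference protein-cluster report: the DNA
#' repair/cell cycle cluster of 20 proteins, two extracellular-matrix
#' clusters, the TGF-beta signaling cluster and the base-excision repair
#' pair, with their pathway annotations.
#'
#' @return A data.frame with `cluster_id`, `gene_count`, `genes`
#'   (comma-separated), `pathways`.
#' @export
table1_clusters <- function() {
  df <- utils::read.delim(system.file("extdata", "table1_clusters.tsv",
                                      package = "varcascade"),
                          sep = "\t", stringsAsFactors = FALSE)
  df
}

#' Packaged seed list of known CRC predisposition genes
#'
#' The known colorectal cancer predisposition genes named in the reference
#' cluster report (mismatch repair genes, base-excision repair genes and
#' TGF-beta pathway genes). The published analysis used a 16-gene list of
#' which these 11 are printed; replace via [read_seed_genes()] when the
#' full list is available.
#'
#' @return Character vector of gene symbols.
#' @export
crc_seed_genes <- function() {
  read_seed_genes(system.file("extdata", "crc_seed_genes.txt",
                              package = "varcascade"))
}
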