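#' Default mapping from VEP-style annotation sub-fields to cohort columns
#'
#' The per-transcript annotation INFO field (VEP `CSQ`) is a pipe-delimited
#' block per transcript; this map declares which sub-field feeds which
#' cohort column. Override any entry to match a custom VEP invocation.
#'
#' @return Named character vector: names are cohort columns, values are
#'   annotation sub-field names.
#' @export
default_vcf_field_map <- function() {
  c(
    gene_symbol = "SYMBOL", transcript_id = "Feature",
    is_canonical = "CANONICAL", consequence_terms = "Consequence",
    hgvs_c = "HGVSc", hgvs_p = "HGVSp",
    exon = "EXON", intron = "INTRON",
    af_global = "gnomAD_exomes_AF", af_nfe = "gnomAD_exomes_NFE_AF",
    af_popmax = "gnomAD_exomes_POPMAX_AF",
    cadd_phred = "CADD_PHRED",
    call_sift = "SIFT_pred", call_polyphen2 = "Polyphen2_HDIV_pred",
    call_lrt = "LRT_pred", call_mutation_taster = "MutationTaster_pred",
    call_mutation_assessor = "MutationAssessor_pred",
    call_fathmm = "FATHMM_pred", call_metasvm = "MetaSVM_pred",
    call_metalr = "MetaLR_pred", call_provean = "PROVEAN_pred",
    gerp = "GERP", phastcons = "PhastCons", phylop = "PhyloP",
    missense_z = "gnomAD_mis_z", alphamissense = "am_pathogenicity",
    revel = "REVEL", mutpred2_score = "MutPred2_score",
    mutpred2_mechanisms = "MutPred2_mechanisms",
    spliceai_ag = "SpliceAI_pred_DS_AG", spliceai_al = "SpliceAI_pred_DS_AL",
    spliceai_dg = "SpliceAI_pred_DS_DG", spliceai_dl = "SpliceAI_pred_DS_DL",
    mmsplice = "MMSplice_delta_logit_psi", loeuf = "LOEUF"
  )
}

#' Read a VEP-annotated VCF into the cohort model
#'
#' Reads a VCF 4.x file whose INFO carries a pipe-delimited per-transcript
#' annotation string (VEP's `CSQ`), keeps only transcript blocks flagged
#' canonical, and returns one cohort row per (variant, canonical transcript)
#' pair. Multi-allelic records are split one alternate allele per row; when
#' the annotation declares an `Allele` sub-field, transcript blocks are
#' matched to their allele, otherwise every block is considered for every
#' allele. Empty annotation sub-fields become absent values, never zero.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param field_map Named character vector mapping cohort columns to
#'   annotation sub-field names, as [default_vcf_field_map()].
#' @param info_key Name of the per-transcript annotation INFO field.
#' @param family_id Family identifier attached to every variant (single
#'   sample per file in this design).
#' @param csq_fields Sub-field order of the annotation string. `NULL`
#'   (default) parses it from the `Format:` clause of the INFO header line.
#' @return A `variant_table` with one row per variant on its canonical
#'   transcript.
#' @export
read_vep_vcf <- function(path, field_map = default_vcf_field_map(),
                         info_key = "CSQ", family_id = "UNKNOWN",
                         csq_fields = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vep_vcf() requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)

  if (is.null(csq_fields)) {
    meta <- vcf@meta
    ln <- grep(paste0("^##INFO=<ID=", info_key, ","), meta, value = TRUE)
    if (length(ln) == 0) {
      stop("INFO field '", info_key, "' not declared in the VCF header; ",
           "pass csq_fields explicitly")
    }
    fmt <- sub('.*Format: ?([^">]+).*', "\\1", ln[1])
    csq_fields <- strsplit(fmt, "|", fixed = TRUE)[[1]]
  }

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    rec <- fix[i, ]
    alts <- strsplit(rec$ALT, ",", fixed = TRUE)[[1]]
    info <- rec$INFO
    csq_raw <- extract_info_value(info, info_key)
    if (is.na(csq_raw)) next
    blocks <- strsplit(csq_raw, ",", fixed = TRUE)[[1]]
    parsed <- lapply(blocks, function(b) {
      vals <- strsplit(b, "|", fixed = TRUE)[[1]]
      if (length(vals) > length(csq_fields)) {
        stop(sprintf(
          "annotation sub-field count mismatch at %s:%s (%d fields, %d declared)",
          rec$CHROM, rec$POS, length(vals), length(csq_fields)))
      }
      length(vals) <- length(csq_fields)  # trailing empties are dropped by VEP
      stats::setNames(vals, csq_fields)
    })
    for (alt in alts) {
      keep <- parsed
      if ("Allele" %in% csq_fields && length(alts) > 1) {
        matched <- Filter(function(v) identical(unname(v[["Allele"]]), alt),
                          parsed)
        if (length(matched) > 0) keep <- matched
      }
      for (v in keep) {
        canon <- if ("CANONICAL" %in% names(v)) {
          !is.na(v[["CANONICAL"]]) && toupper(v[["CANONICAL"]]) == "YES"
        } else TRUE
        if (!canon) next
        rows[[length(rows) + 1]] <- csq_to_row(rec, alt, v, field_map,
                                               family_id)
      }
    }
  }
  if (length(rows) == 0) {
    df <- empty_cohort()
  } else {
    df <- do.call(rbind, rows)
  }
  variant_table(df)
}

extract_info_value <- function(info, key) {
  fields <- strsplit(info, ";", fixed = TRUE)[[1]]
  hit <- grep(paste0("^", key, "="), fields, value = TRUE)
  if (length(hit) == 0) return(NA_character_)
  sub(paste0("^", key, "="), "", hit[1])
}

csq_to_row <- function(rec, alt, v, field_map, family_id) {
  g <- function(sub) {
    if (!sub %in% names(v)) return(NA_character_)
    val <- unname(v[[sub]])
    if (is.na(val) || !nzchar(val)) NA_character_ else val
  }
  row <- data.frame(
    variant_id = paste(rec$CHROM, rec$POS, rec$REF, alt, sep = "_"),
    chrom = rec$CHROM, pos = rec$POS, ref = rec$REF, alt = alt,
    family_id = family_id, stringsAsFactors = FALSE
  )
  for (col in names(field_map)) {
    sub <- field_map[[col]]
    if (col == "exon") {
      rk <- parse_rank_fraction(g(sub))
      row$exon_index <- rk[1, "index"]
      row$exon_total <- rk[1, "total"]
    } else if (col == "intron") {
      rk <- parse_rank_fraction(g(sub))
      row$intron_index <- rk[1, "index"]
      row$intron_total <- rk[1, "total"]
    } else if (col == "is_canonical") {
      val <- g(sub)
      row$is_canonical <- !is.na(val) && toupper(val) == "YES"
    } else if (col == "consequence_terms") {
      row$consequence_terms <- g(sub)
    } else {
      row[[col]] <- g(sub)
    }
  }
  if (is.na(row$consequence_terms)) row$consequence_terms <- "unknown"
  row
}

empty_cohort <- function() {
  dict <- cohort_columns()
  df <- as.data.frame(
    stats::setNames(
      lapply(dict$type, function(t) vector(switch(t, numeric = "numeric",
                                                  integer = "integer",
                                                  logical = "logical",
                                                  "character"), 0)),
      dict$column),
    check.names = FALSE)
  df
}
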