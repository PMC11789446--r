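## Universal cascade gates. Each gate is vectorized over variants and
## returns a decision vector in {PASS, FAIL, EXCLUDED} plus the evidence it
## looked at, so the cascade can assemble a per-variant audit trace.

gate_decisions <- c("PASS", "FAIL", "EXCLUDED", "NOT_APPLICABLE")

#' Population allele-frequency gate
#'
#' A variant passes when it is rare in the reference population: under the
#' default `"all"` mode every *present* frequency field (gnomAD exomes
#' global, NFE and popmax) must be strictly below `maf_max`; under `"any"`
#' mode one field below the cutoff suffices. A variant with no frequency at
#' all passes — absence from gnomAD means the allele was not observed, which
#' is the strongest rarity evidence available, never a zero to be compared.
#'
#' @param af_global,af_nfe,af_popmax Numeric vectors of allele frequencies
#'   in `[0,1]`; `NA` = not observed.
#' @param config A [threshold_config()] (or named list of overrides).
#' @return A list with `decision` (character vector) and `evidence` (a
#'   data.frame echoing the frequencies and the threshold applied).
#' @export
maf_gate <- function(af_global = NA_real_, af_nfe = NA_real_,
                     af_popmax = NA_real_, config = NULL) {
  t <- as_threshold_config(config)
  n <- max(length(af_global), length(af_nfe), length(af_popmax))
  af <- cbind(rep_len(as.numeric(af_global), n),
              rep_len(as.numeric(af_nfe), n),
              rep_len(as.numeric(af_popmax), n))
  if (any(af < 0, na.rm = TRUE)) stop("negative allele frequency")
  below <- af < t$maf_max
  if (t$maf_mode == "all") {
    ok <- apply(below, 1, function(r) all(r[!is.na(r)]))
  } else {
    ok <- apply(below, 1, function(r) {
      if (all(is.na(r))) TRUE else any(r[!is.na(r)])
    })
  }
  list(
    decision = ifelse(ok, "PASS", "FAIL"),
    evidence = data.frame(af_global = af[, 1], af_nfe = af[, 2],
                          af_popmax = af[, 3],
                          maf_max = rep(t$maf_max, n),
                          maf_mode = rep(t$maf_mode, n))
  )
}

#' CADD deleteriousness gate
#'
#' Keeps variants in the top tier of predicted deleteriousness: the scaled
#' PHRED-like CADD score must be strictly greater than `cadd_min`
#' (default 20, the top 1% of possible substitutions). The gate is an
#' inclusion criterion, so a variant without a CADD score fails — missing
#' evidence cannot demonstrate deleteriousness.
#'
#' @param cadd_phred Numeric vector of scaled CADD scores; `NA` = absent.
#' @inheritParams maf_gate
#' @return A list with `decision` and `evidence` as in [maf_gate()].
#' @export
cadd_gate <- function(cadd_phred, config = NULL) {
  t <- as_threshold_config(config)
  cadd_phred <- as.numeric(cadd_phred)
  ok <- !is.na(cadd_phred) & cadd_phred > t$cadd_min
  list(
    decision = ifelse(ok, "PASS", "FAIL"),
    evidence = data.frame(cadd_phred = cadd_phred,
                          cadd_min = rep(t$cadd_min, length(cadd_phred)))
  )
}

#' Last-exon exclusion for protein-truncating variants
#'
#' Stop-gain and frameshift variants in the last exon of a transcript often
#' escape nonsense-mediated decay, so the cascade excludes them from
#' further analysis. The decision is EXCLUDED when the affected exon rank
#' equals the transcript's exon count, PASS otherwise; when exon information
#' is absent the variant passes with a warning recorded in the evidence.
#'
#' @param exon_index,exon_total Integer vectors: rank of the affected exon
#'   and number of exons in the transcript.
#' @return A list with `decision`, `evidence` (including a
#'   `missing_exon_info` warning flag).
#' @export
last_exon_gate <- function(exon_index, exon_total) {
  exon_index <- as.integer(exon_index)
  exon_total <- rep_len(as.integer(exon_total), length(exon_index))
  known <- !is.na(exon_index) & !is.na(exon_total)
  last <- known & exon_index == exon_total
  list(
    decision = ifelse(last, "EXCLUDED", "PASS"),
    evidence = data.frame(exon_index = exon_index, exon_total = exon_total,
                          missing_exon_info = !known)
  )
}
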