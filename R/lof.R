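## Loss-of-function evidence tiers. These annotate truncating and splice
## variants that already passed the frequency and CADD gates; per design
## they never change a variant's survived status.

#' MutPred2 pathogenicity tier for truncating variants
#'
#' MutPred2 returns a score in `[0, 1]`; 0.50 is the recommended
#' conservative threshold at a 5% false-positive rate. The threshold is
#' inclusive: a variant scoring exactly 0.50 is tiered LIKELY_PATHOGENIC.
#' Scored variants below the threshold are tiered BELOW_THRESHOLD but still
#' reported — the tier discriminates, it does not exclude.
#'
#' @param score Numeric vector of MutPred2 scores (`NA` = not scored).
#' @param config A [threshold_config()]; `mutpred2_min` is used.
#' @return Character vector in
#'   `{LIKELY_PATHOGENIC, BELOW_THRESHOLD, NOT_SCORED}`.
#' @export
mutpred2_tier <- function(score, config = NULL) {
  t <- as_threshold_config(config)
  score <- as.numeric(score)
  if (any(score < 0 | score > 1, na.rm = TRUE)) {
    stop("MutPred2 score outside [0, 1]")
  }
  ifelse(is.na(score), "NOT_SCORED",
         ifelse(score >= t$mutpred2_min, "LIKELY_PATHOGENIC",
                "BELOW_THRESHOLD"))
}

#' SpliceAI tier from the four delta scores
#'
#' The tier is taken over the maximum of the four deltas (acceptor gain,
#' acceptor loss, donor gain, donor loss): a maximum delta >= 0.8 is a
#' high-scoring predicted cryptic splice variant (HIGH), >= 0.5 a
#' confidently predicted one (CONFIDENT), anything lower LOW; a variant
#' with no delta at all is NOT_SCORED. The channel attaining the maximum is
#' reported alongside the tier.
#'
#' @param acceptor_gain,acceptor_loss,donor_gain,donor_loss Numeric vectors
#'   of deltas in `[0, 1]` (`NA` = absent).
#' @inheritParams mutpred2_tier
#' @return A data.frame with `tier`, `max_delta` and `channel`.
#' @export
spliceai_tier <- function(acceptor_gain = NA_real_, acceptor_loss = NA_real_,
                          donor_gain = NA_real_, donor_loss = NA_real_,
                          config = NULL) {
  t <- as_threshold_config(config)
  n <- max(length(acceptor_gain), length(acceptor_loss),
           length(donor_gain), length(donor_loss))
  m <- cbind(acceptor_gain = rep_len(as.numeric(acceptor_gain), n),
             acceptor_loss = rep_len(as.numeric(acceptor_loss), n),
             donor_gain = rep_len(as.numeric(donor_gain), n),
             donor_loss = rep_len(as.numeric(donor_loss), n))
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    stop("SpliceAI delta outside [0, 1]")
  }
  all_na <- apply(m, 1, function(r) all(is.na(r)))
  max_delta <- suppressWarnings(apply(m, 1, max, na.rm = TRUE))
  max_delta[all_na] <- NA_real_
  channel <- rep(NA_character_, n)
  channel[!all_na] <- colnames(m)[apply(m[!all_na, , drop = FALSE], 1,
                                        which.max)]
  tier <- ifelse(all_na, "NOT_SCORED",
                 ifelse(max_delta >= t$spliceai_high, "HIGH",
                        ifelse(max_delta >= t$spliceai_confident,
                               "CONFIDENT", "LOW")))
  data.frame(tier = tier, max_delta = max_delta, channel = channel)
}

#' MMSplice confidence tier
#'
#' MMSplice reports a signed effect size on splicing efficiency; confidence
#' is read from the absolute value: strictly above 2 is HIGH confidence,
#' strictly above 1.5 MEDIUM, anything else LOW; absent scores are
#' NOT_SCORED.
#'
#' @param score Numeric vector of signed MMSplice scores (`NA` = absent).
#' @inheritParams mutpred2_tier
#' @return Character vector in `{HIGH, MEDIUM, LOW, NOT_SCORED}`.
#' @export
mmsplice_tier <- function(score, config = NULL) {
  t <- as_threshold_config(config)
  a <- abs(as.numeric(score))
  ifelse(is.na(a), "NOT_SCORED",
         ifelse(a > t$mmsplice_high, "HIGH",
                ifelse(a > t$mmsplice_medium, "MEDIUM", "LOW")))
}

#' Gene-constraint flag from LOEUF
#'
#' Flags the gene of a loss-of-function variant as constrained when its
#' LOEUF (loss-of-function observed/expected upper bound fraction) is
#' strictly below 0.6, the cutoff gnomAD recommends when one is needed.
#' Note that several established tumor suppressors — the mismatch repair
#' genes among them — exceed 0.6, so the flag is supporting evidence, not a
#' filter.
#'
#' @param loeuf Numeric vector of LOEUF values (`NA` = absent, fails the
#'   flag).
#' @inheritParams mutpred2_tier
#' @return Logical vector.
#' @export
loeuf_flag <- function(loeuf, config = NULL) {
  t <- as_threshold_config(config)
  loeuf <- as.numeric(loeuf)
  if (any(loeuf < 0, na.rm = TRUE)) stop("negative LOEUF")
  !is.na(loeuf) & loeuf < t$loeuf_max
}

#' Assemble the loss-of-function evidence block for a cohort
#'
#' Convenience wrapper computing every LoF tier for the relevant columns of
#' a cohort table. Splice tiers are computed only where SpliceAI/MMSplice
#' scores exist; truncating variants without a MutPred2 score stay
#' NOT_SCORED.
#'
#' @param df A `variant_table`.
#' @inheritParams mutpred2_tier
#' @return A data.frame aligned with `df`: `mutpred2_tier`, `splice_tier`,
#'   `splice_channel`, `spliceai_max_delta`, `mmsplice_tier`,
#'   `gene_constrained`.
#' @export
lof_evidence <- function(df, config = NULL) {
  t <- as_threshold_config(config)
  n <- nrow(df)
  col <- function(nm) if (nm %in% names(df)) df[[nm]] else rep(NA_real_, n)
  sai <- spliceai_tier(col("spliceai_ag"), col("spliceai_al"),
                       col("spliceai_dg"), col("spliceai_dl"), t)
  data.frame(
    mutpred2_tier = mutpred2_tier(col("mutpred2_score"), t),
    splice_tier = sai$tier,
    splice_channel = sai$channel,
    spliceai_max_delta = sai$max_delta,
    mmsplice_tier = mmsplice_tier(col("mmsplice"), t),
    gene_constrained = loeuf_flag(col("loeuf"), t)
  )
}
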