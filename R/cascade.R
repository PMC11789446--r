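#' Run the full variant prioritization cascade
#'
#' Orchestrates the gates of the prioritization pipeline over an annotated
#' cohort. Every variant first passes the population-frequency gate and the
#' CADD gate; it is then routed by class: missense variants face the
#' nine-tool consensus deleteriousness vote and the conservation vote (and
#' survivors receive the constraint / AlphaMissense / REVEL annotation);
#' stop-gain and frameshift variants face the last-exon exclusion and are
#' then annotated with loss-of-function evidence tiers; canonical splice
#' variants receive the splice evidence tiers with no further exclusion;
#' variants of any other class are dropped with a count. Annotation steps
#' never change survival.
#'
#' @param cohort A `variant_table` (or data.frame accepted by
#'   [variant_table()]).
#' @param config A [threshold_config()], a named list of overrides, or
#'   `NULL` for defaults.
#' @param weights Predictor call weight mapping, see
#'   [default_call_weights()].
#' @return A `cascade_result`: a list with
#'   \describe{
#'     \item{variants}{the cohort with `variant_class`, per-gate decisions,
#'       evidence tiers and `survived` appended;}
#'     \item{trace}{long data.frame (`variant_id`, `gate`, `decision`) — the
#'       ordered audit of each gate a variant reached; a FAIL or EXCLUDED
#'       decision terminates a variant's trace;}
#'     \item{summary}{per class and gate: variants entering, passing and
#'       failing (entering = passing + failing at every gate);}
#'     \item{config}{the effective `threshold_config`.}
#'   }
#' @examples
#' fx <- table2_variants()
#' res <- run_cascade(fx)
#' sum(res$variants$survived)
#' @export
run_cascade <- function(cohort, config = NULL,
                        weights = default_call_weights()) {
  t <- as_threshold_config(config)
  df <- if (inherits(cohort, "variant_table")) cohort else variant_table(cohort)
  n <- nrow(df)
  col_num <- function(nm) if (nm %in% names(df)) as.numeric(df[[nm]]) else rep(NA_real_, n)
  col_int <- function(nm) if (nm %in% names(df)) as.integer(df[[nm]]) else rep(NA_integer_, n)

  cls <- classify_variants(df)
  vclass <- as.character(cls$variant_class)

  maf <- maf_gate(col_num("af_global"), col_num("af_nfe"),
                  col_num("af_popmax"), t)
  cadd <- cadd_gate(col_num("cadd_phred"), t)
  vote <- deleteriousness_vote(df, t, weights)
  cons <- conservation_vote(col_num("gerp"), col_num("phastcons"),
                            col_num("phylop"), t)
  lastx <- last_exon_gate(col_int("exon_index"), col_int("exon_total"))
  constr <- constraint_annotation(col_num("missense_z"),
                                  col_num("alphamissense"),
                                  col_num("revel"), t)
  lof <- lof_evidence(df, t)

  trace_rows <- list()
  active <- rep(TRUE, n)
  add_gate <- function(gate, attempted, decision) {
    idx <- which(attempted)
    if (length(idx) > 0) {
      trace_rows[[length(trace_rows) + 1]] <<- data.frame(
        variant_id = df$variant_id[idx], gate = gate,
        variant_class = vclass[idx], decision = decision[idx],
        stringsAsFactors = FALSE)
    }
    active <<- active & (!attempted | decision == "PASS")
  }

  add_gate("maf", rep(TRUE, n), maf$decision)
  add_gate("cadd", active, cadd$decision)
  add_gate("class_route", active,
           ifelse(vclass == "OTHER", "FAIL", "PASS"))
  is_mis <- vclass == "MISSENSE"
  add_gate("deleteriousness_vote", active & is_mis,
           ifelse(vote$pass, "PASS", "FAIL"))
  add_gate("conservation_vote", active & is_mis,
           ifelse(cons$pass, "PASS", "FAIL"))
  is_trunc <- vclass %in% c("STOP_GAIN", "FRAMESHIFT")
  add_gate("last_exon", active & is_trunc, lastx$decision)

  trace <- if (length(trace_rows) > 0) {
    do.call(rbind, trace_rows)
  } else {
    data.frame(variant_id = character(), gate = character(),
               variant_class = character(), decision = character())
  }

  out <- df
  out$variant_class <- vclass
  out$class_warning <- cls$class_warning
  out$maf_decision <- maf$decision
  out$cadd_decision <- cadd$decision
  out$vote_score <- vote$weight_sum
  out$vote_pass <- vote$pass
  out$conservation_votes <- cons$votes
  out$conservation_pass <- cons$pass
  out$last_exon_decision <- ifelse(is_trunc, lastx$decision,
                                   "NOT_APPLICABLE")
  out$missing_exon_info <- is_trunc & lastx$evidence$missing_exon_info
  out$constrained_gene <- ifelse(is_mis, constr$constrained_gene, NA)
  out$pathogenicity_support <- ifelse(is_mis, constr$pathogenicity_support, NA)
  out$mutpred2_tier <- lof$mutpred2_tier
  out$splice_tier <- lof$splice_tier
  out$splice_channel <- lof$splice_channel
  out$spliceai_max_delta <- lof$spliceai_max_delta
  out$mmsplice_tier <- lof$mmsplice_tier
  out$gene_constrained <- lof$gene_constrained
  out$survived <- active

  structure(
    list(variants = out, trace = trace,
         summary = summarize_trace(trace), config = t),
    class = "cascade_result")
}

summarize_trace <- function(trace) {
  if (nrow(trace) == 0) {
    return(data.frame(variant_class = character(), gate = character(),
                      entering = integer(), passing = integer(),
                      failing = integer()))
  }
  gates <- unique(trace$gate)  # preserves cascade order
  agg <- stats::aggregate(
    cbind(entering = rep(1L, nrow(trace)),
          passing = as.integer(trace$decision == "PASS"),
          failing = as.integer(trace$decision != "PASS")) ~
      variant_class + gate, data = trace, FUN = sum)
  agg$gate <- factor(agg$gate, levels = gates)
  agg <- agg[order(agg$gate, agg$variant_class), ]
  agg$gate <- as.character(agg$gate)
  rownames(agg) <- NULL
  agg
}

#' @export
print.cascade_result <- function(x, ...) {
  v <- x$variants
  cat(sprintf("<cascade_result> %d variants, %d survived\n",
              nrow(v), sum(v$survived)))
  tab <- table(factor(v$variant_class, levels = variant_classes()),
               v$survived)
  print(tab)
  invisible(x)
}

#' Variants surviving the cascade
#'
#' @param result A `cascade_result` from [run_cascade()].
#' @return The rows of `result$variants` with `survived == TRUE`.
#' @export
surviving_variants <- function(result) {
  stopifnot(inherits(result, "cascade_result"))
  out <- result$variants[result$variants$survived, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the prioritized-variant report
#'
#' One row per surviving variant with its class, all evidence fields and a
#' one-line gate trace summary; deterministic column order, so identical
#' inputs and configuration give byte-identical reports. The file
#' round-trips through [read_variant_table()].
#'
#' @param result A `cascade_result`.
#' @param path Output TSV path.
#' @param survivors_only Write only surviving variants (default) or all.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, survivors_only = TRUE) {
  stopifnot(inherits(result, "cascade_result"))
  df <- if (survivors_only) surviving_variants(result) else result$variants
  tr <- result$trace
  path_of <- function(id) {
    rows <- tr[tr$variant_id == id, , drop = FALSE]
    paste(paste0(rows$gate, ":", rows$decision), collapse = ";")
  }
  df$gate_trace <- vapply(df$variant_id, path_of, character(1),
                          USE.NAMES = FALSE)
  write_variant_table(df, path)
}
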