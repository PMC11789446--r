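#' Default categorical-call to vote-weight mapping
#'
#' The nine-tool deleteriousness vote sums one weight per tool in
#' `{0, 0.5, 1}`: a deleterious call contributes 1, an intermediate call
#' (PolyPhen-2 "possibly damaging", MutationAssessor "medium") contributes
#' 0.5, tolerated/benign/neutral calls and missing predictions contribute 0.
#' Calls are matched case-insensitively; dbNSFP-style single letters and
#' spelled-out words are both understood. The mapping is data: it is shipped
#' as `extdata/call_weights.yaml` and any table of the same shape can be
#' passed to [map_tool_call()] / [deleteriousness_vote()]. A call given as a
#' number in `[0, 1]` is used directly as the weight, which accommodates
#' per-tool weight alphabets finer than half steps.
#'
#' @param path YAML file with one map per tool (`call: weight`) plus a
#'   `default` map applied to every tool.
#' @return Named list: one named numeric vector of weights per tool, plus
#'   `default`.
#' @export
default_call_weights <- function(path = system.file("extdata",
                                                    "call_weights.yaml",
                                                    package = "varcascade")) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(m) unlist(m))
}

#' Map one predictor's categorical call to its vote weight
#'
#' @param tool One of [predictor_tools()].
#' @param call Character vector of categorical calls (`NA` = missing).
#' @param weights A weight mapping as [default_call_weights()].
#' @return Numeric vector of weights in `[0, 1]`.
#' @export
map_tool_call <- function(tool, call, weights = default_call_weights()) {
  tool <- tolower(tool)
  if (!tool %in% predictor_tools()) {
    stop("unknown predictor tool: ", tool)
  }
  tab <- c(weights[[tool]], weights[["default"]])
  names(tab) <- tolower(names(tab))
  vapply(as.character(call), function(x) {
    if (is.na(x) || !nzchar(x)) return(0)
    key <- tolower(trimws(x))
    key <- gsub("[ _]+", "_", key)
    if (key %in% names(tab)) return(unname(tab[[key]]))
    num <- suppressWarnings(as.numeric(x))
    if (!is.na(num)) {
      if (num < 0 || num > 1) {
        stop(sprintf("numeric call weight %s for %s outside [0, 1]", x, tool))
      }
      return(num)
    }
    stop(sprintf("unknown call symbol '%s' for tool '%s'", x, tool))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Consensus deleteriousness vote over the nine predictors
#'
#' Sums the per-tool weights of the categorical calls and passes a variant
#' when the vote exceeds 50% of the fixed nine-tool denominator (weight sum
#' strictly greater than 4.5). Missing calls contribute 0 but the
#' denominator stays 9 — a variant cannot pass on a handful of confident
#' tools alone. The printed per-variant score is `weight_sum` over 9
#' ("n/9").
#'
#' @param calls A data.frame carrying the `call_<tool>` columns of the
#'   cohort dialect (extra columns ignored), or a named list/vector keyed by
#'   tool name.
#' @param config A [threshold_config()]; `vote_fraction` and
#'   `vote_denominator` are used.
#' @param weights Weight mapping, see [default_call_weights()].
#' @return A data.frame with one row per variant: `weight_sum`,
#'   `denominator`, `fraction`, `pass`, and one `weight_<tool>` column per
#'   predictor.
#' @export
deleteriousness_vote <- function(calls, config = NULL,
                                 weights = default_call_weights()) {
  t <- as_threshold_config(config)
  tools <- predictor_tools()
  if (!is.data.frame(calls)) {
    calls <- as.list(calls)
    names(calls) <- sub("^call_", "", tolower(names(calls)))
    calls <- as.data.frame(
      stats::setNames(lapply(tools, function(tl) {
        if (tl %in% names(calls)) as.character(calls[[tl]]) else NA_character_
      }), paste0("call_", tools)),
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  n <- nrow(calls)
  w <- matrix(0, nrow = n, ncol = length(tools),
              dimnames = list(NULL, paste0("weight_", tools)))
  for (j in seq_along(tools)) {
    col <- paste0("call_", tools[j])
    if (col %in% names(calls)) {
      w[, j] <- map_tool_call(tools[j], calls[[col]], weights)
    }
  }
  weight_sum <- rowSums(w)
  fraction <- weight_sum / t$vote_denominator
  out <- data.frame(weight_sum = weight_sum,
                    denominator = rep(t$vote_denominator, n),
                    fraction = fraction,
                    pass = fraction > t$vote_fraction)
  cbind(out, as.data.frame(w))
}

#' Conservation vote over GERP, PhastCons and PhyloP
#'
#' A missense candidate must sit at an evolutionarily conserved position:
#' each of GERP (> 2.0, strict), PhastCons (> 0.3, strict) and PhyloP
#' (>= 3.0, inclusive) casts one vote, an absent score casts none, and the
#' variant passes with at least `conservation_min_votes` (default 2)
#' positive votes.
#'
#' @param gerp,phastcons,phylop Numeric score vectors (`NA` = absent).
#' @inheritParams deleteriousness_vote
#' @return A data.frame with per-score flags (`gerp_vote`, `phastcons_vote`,
#'   `phylop_vote`), the vote count `votes`, and `pass`.
#' @export
conservation_vote <- function(gerp = NA_real_, phastcons = NA_real_,
                              phylop = NA_real_, config = NULL) {
  t <- as_threshold_config(config)
  n <- max(length(gerp), length(phastcons), length(phylop))
  gerp <- rep_len(as.numeric(gerp), n)
  phastcons <- rep_len(as.numeric(phastcons), n)
  phylop <- rep_len(as.numeric(phylop), n)
  gv <- !is.na(gerp) & gerp > t$gerp_min
  pv <- !is.na(phastcons) & phastcons > t$phastcons_min
  yv <- !is.na(phylop) & phylop >= t$phylop_min
  votes <- gv + pv + yv
  data.frame(gerp_vote = gv, phastcons_vote = pv, phylop_vote = yv,
             votes = votes, pass = votes >= t$conservation_min_votes)
}

#' Constraint and supporting pathogenicity annotation for missense survivors
#'
#' Purely annotative step attached to missense variants that passed the
#' vote and conservation gates: the gnomAD missense constraint Z-score flags
#' the gene as constrained when positive, and the AlphaMissense and REVEL
#' scores are echoed with a combined `pathogenicity_support` flag (either
#' score at or above its reporting cutoff). This step never excludes a
#' variant.
#'
#' @param missense_z,alphamissense,revel Numeric vectors (`NA` = absent).
#' @inheritParams deleteriousness_vote
#' @return A data.frame with `constrained_gene`, `alphamissense`, `revel`,
#'   `pathogenicity_support`.
#' @export
constraint_annotation <- function(missense_z = NA_real_,
                                  alphamissense = NA_real_,
                                  revel = NA_real_, config = NULL) {
  t <- as_threshold_config(config)
  n <- max(length(missense_z), length(alphamissense), length(revel))
  missense_z <- rep_len(as.numeric(missense_z), n)
  alphamissense <- rep_len(as.numeric(alphamissense), n)
  revel <- rep_len(as.numeric(revel), n)
  am <- !is.na(alphamissense) & alphamissense >= t$alphamissense_min
  rv <- !is.na(revel) & revel >= t$revel_min
  data.frame(
    constrained_gene = !is.na(missense_z) & missense_z > 0,
    alphamissense = alphamissense, revel = revel,
    pathogenicity_support = am | rv
  )
}
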