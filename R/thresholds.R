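#' Numeric cutoffs of the prioritization cascade
#'
#' Every threshold used by the filtering cascade, the loss-of-function
#' evidence tiers and the network stage, externalized in one object so a run
#' is fully described by its configuration. Defaults follow the published
#' pipeline: variants are kept when rare (all observed gnomAD exome
#' frequencies below 0.1%) and predicted deleterious (scaled PHRED-like CADD
#' strictly above 20); missense variants additionally need a consensus
#' deleteriousness vote above 50% of nine tools and at least two of three
#' conservation calls (GERP > 2.0, PhastCons > 0.3, PhyloP >= 3.0).
#'
#' Strictness follows the wording each cutoff was stated with: `cadd_min`,
#' `gerp_min`, `phastcons_min` and `vote_fraction` are strict (`>`);
#' `phylop_min`, `mutpred2_min`, the two SpliceAI tiers and
#' `string_min_score` are inclusive (`>=`); `loeuf_max` is strict (`<`);
#' the MMSplice tiers are strict on the absolute score.
#'
#' @param maf_max Maximum population allele frequency; a variant fails when
#'   any present gnomAD field is at or above this fraction. Default 0.001.
#' @param cadd_min Minimum scaled CADD PHRED score (strict). Default 20.
#' @param maf_mode `"all"` (default) requires every present frequency field
#'   below `maf_max`; `"any"` requires at least one.
#' @param vote_fraction Fraction of the nine-tool deleteriousness vote that
#'   must be exceeded (strict). Default 0.5.
#' @param vote_denominator Denominator of the vote; fixed at 9 tools
#'   regardless of missingness by default.
#' @param gerp_min,phastcons_min,phylop_min Conservation cutoffs (GERP and
#'   PhastCons strict, PhyloP inclusive).
#' @param conservation_min_votes Positive conservation calls required.
#' @param alphamissense_min,revel_min Reporting cutoffs for supporting
#'   missense pathogenicity evidence (annotation only, never exclusion).
#' @param mutpred2_min MutPred2 score tiering LIKELY_PATHOGENIC (inclusive).
#' @param spliceai_confident,spliceai_high SpliceAI delta tiers (inclusive).
#' @param mmsplice_medium,mmsplice_high MMSplice absolute-score tiers
#'   (strict).
#' @param loeuf_max LOEUF below which a gene is flagged constrained
#'   (strict).
#' @param string_min_score Minimum combined interaction score for an edge to
#'   enter the network (inclusive). Default 0.400.
#' @param string_prior Random-interaction prior removed before channel
#'   combination and re-added afterwards. Default 0.041.
#' @param mcl_inflation,mcl_expansion,mcl_max_iter,mcl_tol Markov clustering
#'   parameters (see [mcl_cluster()]).
#' @param fdr_alpha Significance level applied to Benjamini-Hochberg
#'   adjusted enrichment q-values.
#'
#' @return An object of class `threshold_config` (a validated named list).
#' @seealso [read_threshold_config()], [write_threshold_config()]
#' @examples
#' cfg <- threshold_config(maf_max = 0.0005)
#' cfg$maf_max
#' @export
threshold_config <- function(maf_max = 0.001,
                             cadd_min = 20,
                             maf_mode = c("all", "any"),
                             vote_fraction = 0.5,
                             vote_denominator = 9,
                             gerp_min = 2.0,
                             phastcons_min = 0.3,
                             phylop_min = 3.0,
                             conservation_min_votes = 2,
                             alphamissense_min = 0.564,
                             revel_min = 0.5,
                             mutpred2_min = 0.50,
                             spliceai_confident = 0.5,
                             spliceai_high = 0.8,
                             mmsplice_medium = 1.5,
                             mmsplice_high = 2.0,
                             loeuf_max = 0.6,
                             string_min_score = 0.400,
                             string_prior = 0.041,
                             mcl_inflation = 3.0,
                             mcl_expansion = 2L,
                             mcl_max_iter = 100L,
                             mcl_tol = 1e-6,
                             fdr_alpha = 0.05) {
  maf_mode <- match.arg(maf_mode)
  cfg <- list(
    maf_max = maf_max, cadd_min = cadd_min, maf_mode = maf_mode,
    vote_fraction = vote_fraction, vote_denominator = vote_denominator,
    gerp_min = gerp_min, phastcons_min = phastcons_min,
    phylop_min = phylop_min,
    conservation_min_votes = conservation_min_votes,
    alphamissense_min = alphamissense_min, revel_min = revel_min,
    mutpred2_min = mutpred2_min,
    spliceai_confident = spliceai_confident, spliceai_high = spliceai_high,
    mmsplice_medium = mmsplice_medium, mmsplice_high = mmsplice_high,
    loeuf_max = loeuf_max,
    string_min_score = string_min_score, string_prior = string_prior,
    mcl_inflation = mcl_inflation, mcl_expansion = as.integer(mcl_expansion),
    mcl_max_iter = as.integer(mcl_max_iter), mcl_tol = mcl_tol,
    fdr_alpha = fdr_alpha
  )
  validate_threshold_config(cfg)
  structure(cfg, class = "threshold_config")
}

validate_threshold_config <- function(cfg) {
  stopifnot(
    is.numeric(cfg$maf_max), cfg$maf_max >= 0, cfg$maf_max <= 1,
    cfg$maf_mode %in% c("all", "any"),
    cfg$vote_fraction >= 0, cfg$vote_fraction <= 1,
    cfg$vote_denominator > 0,
    cfg$spliceai_confident <= cfg$spliceai_high,
    cfg$mmsplice_medium <= cfg$mmsplice_high,
    cfg$loeuf_max > 0,
    cfg$string_min_score >= 0, cfg$string_min_score <= 1,
    cfg$string_prior >= 0, cfg$string_prior < 1,
    cfg$mcl_inflation > 1, cfg$mcl_expansion >= 2,
    cfg$fdr_alpha > 0, cfg$fdr_alpha <= 1
  )
  invisible(cfg)
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("<threshold_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}

#' Read or write a threshold configuration as YAML
#'
#' Serializes every cutoff of a [threshold_config()] so a run can be
#' reproduced from its configuration file. Unknown keys in the file are
#' rejected; absent keys fall back to the package defaults.
#'
#' @param path Path to a YAML file.
#' @return `read_threshold_config()` returns a `threshold_config`;
#'   `write_threshold_config()` returns `path` invisibly.
#' @export
read_threshold_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(threshold_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown threshold key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(threshold_config, raw)
}

#' @rdname read_threshold_config
#' @param cfg A `threshold_config`.
#' @export
write_threshold_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "threshold_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

as_threshold_config <- function(cfg) {
  if (is.null(cfg)) return(threshold_config())
  if (inherits(cfg, "threshold_config")) return(cfg)
  if (is.list(cfg)) return(do.call(threshold_config, cfg))
  stop("`config` must be a threshold_config, a named list, or NULL")
}
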