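#' @keywords internal
"_PACKAGE"

## The nine consensus deleteriousness predictors, in canonical order.
#' Names of the nine consensus deleteriousness predictors
#'
#' The fixed tool set whose categorical calls feed the missense
#' deleteriousness vote: SIFT, PolyPhen-2, LRT, MutationTaster,
#' MutationAssessor, FATHMM, MetaSVM, MetaLR and PROVEAN. The vote
#' denominator is the length of this set (9) regardless of missing calls.
#'
#' @return Character vector of the nine tool identifiers.
#' @export
predictor_tools <- function() {
  c("sift", "polyphen2", "lrt", "mutation_taster", "mutation_assessor",
    "fathmm", "metasvm", "metalr", "provean")
}

predictor_call_columns <- function() paste0("call_", predictor_tools())

#' Variant classes handled by the cascade
#'
#' Classes are assigned with precedence CANONICAL_SPLICE > STOP_GAIN >
#' FRAMESHIFT > MISSENSE > OTHER; each variant gets exactly one.
#'
#' @return Character vector of class labels in precedence order.
#' @export
variant_classes <- function() {
  c("CANONICAL_SPLICE", "STOP_GAIN", "FRAMESHIFT", "MISSENSE", "OTHER")
}

#' Column dictionary of the annotated cohort table
#'
#' The flat (TSV) dialect carries one row per variant on its canonical
#' transcript. `variant_id`, `family_id`, `gene_symbol` and
#' `consequence_terms` are mandatory; every other column may be absent, and
#' absent cells ("NA" or empty) always mean "not annotated", never zero.
#'
#' @return A data.frame with columns `column`, `type`, `mandatory`,
#'   `description`.
#' @export
cohort_columns <- function() {
  num <- function(x) rep("numeric", length(x))
  cols <- rbind(
    data.frame(column = c("variant_id", "chrom", "ref", "alt", "family_id",
                          "gene_symbol", "transcript_id", "consequence_terms",
                          "hgvs_c", "hgvs_p", "mutpred2_mechanisms"),
               type = "character"),
    data.frame(column = c("pos", "exon_index", "exon_total",
                          "intron_index", "intron_total"),
               type = "integer"),
    data.frame(column = "is_canonical", type = "logical"),
    data.frame(column = predictor_call_columns(), type = "character"),
    data.frame(column = c("af_global", "af_nfe", "af_popmax", "cadd_phred",
                          "gerp", "phastcons", "phylop", "missense_z",
                          "alphamissense", "revel", "mutpred2_score",
                          "spliceai_ag", "spliceai_al", "spliceai_dg",
                          "spliceai_dl", "mmsplice", "loeuf"),
               type = "numeric")
  )
  cols$mandatory <- cols$column %in%
    c("variant_id", "family_id", "gene_symbol", "consequence_terms")
  desc <- c(
    variant_id = "chrom_pos_ref_alt identifier, unique within a cohort",
    chrom = "chromosome name", ref = "reference allele",
    alt = "alternate allele (one per row)",
    family_id = "index-case family identifier",
    gene_symbol = "HGNC gene symbol on the canonical transcript",
    transcript_id = "Ensembl canonical transcript",
    consequence_terms = "&-separated Sequence Ontology consequence terms",
    hgvs_c = "coding HGVS", hgvs_p = "protein HGVS",
    mutpred2_mechanisms = "semicolon list: Mechanism (p=value)",
    pos = "1-based VCF position",
    exon_index = "affected exon rank", exon_total = "exons in transcript",
    intron_index = "affected intron rank",
    intron_total = "introns in transcript",
    is_canonical = "canonical-transcript flag",
    af_global = "gnomAD exomes global allele frequency",
    af_nfe = "gnomAD exomes non-Finnish European allele frequency",
    af_popmax = "gnomAD exomes popmax allele frequency",
    cadd_phred = "scaled PHRED-like CADD score",
    gerp = "GERP conservation score",
    phastcons = "PhastCons score in [0,1]",
    phylop = "PhyloP score",
    missense_z = "gnomAD gene-level missense constraint Z",
    alphamissense = "AlphaMissense pathogenicity score",
    revel = "REVEL pathogenicity score",
    mutpred2_score = "MutPred2 loss-of-function score",
    spliceai_ag = "SpliceAI acceptor-gain delta",
    spliceai_al = "SpliceAI acceptor-loss delta",
    spliceai_dg = "SpliceAI donor-gain delta",
    spliceai_dl = "SpliceAI donor-loss delta",
    mmsplice = "MMSplice signed delta-logit-psi",
    loeuf = "gnomAD LOEUF gene constraint"
  )
  calls <- predictor_call_columns()
  desc[calls] <- paste("categorical call of", predictor_tools())
  cols$description <- unname(desc[cols$column])
  rownames(cols) <- NULL
  cols
}

#' Validate an annotated cohort table
#'
#' Checks mandatory columns, coerces declared types, and enforces the model
#' invariants: positions >= 1, allele frequencies / PhastCons / SpliceAI
#' deltas / MutPred2 scores within [0,1], exon and intron rank not above the
#' respective total, non-negative LOEUF and CADD, and unique `variant_id`.
#' Columns outside the dictionary are preserved untouched.
#'
#' @param df A data.frame in the cohort dialect.
#' @return The validated data.frame, classed `variant_table`.
#' @export
variant_table <- function(df) {
  stopifnot(is.data.frame(df))
  dict <- cohort_columns()
  missing_mand <- setdiff(dict$column[dict$mandatory], names(df))
  if (length(missing_mand) > 0) {
    stop("cohort table lacks mandatory column(s): ",
         paste(missing_mand, collapse = ", "))
  }
  for (i in seq_len(nrow(dict))) {
    col <- dict$column[i]
    if (!col %in% names(df)) next
    df[[col]] <- coerce_column(df[[col]], dict$type[i], col)
  }
  if (anyDuplicated(df$variant_id)) {
    dup <- unique(df$variant_id[duplicated(df$variant_id)])
    stop("duplicate variant_id in cohort: ", paste(dup, collapse = ", "))
  }
  check_range <- function(col, lo, hi) {
    if (!col %in% names(df)) return(invisible())
    bad <- which(!is.na(df[[col]]) & (df[[col]] < lo | df[[col]] > hi))
    if (length(bad) > 0) {
      stop(sprintf("column '%s' outside [%g, %g] at row(s) %s",
                   col, lo, hi, paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  for (col in c("af_global", "af_nfe", "af_popmax", "phastcons",
                "alphamissense", "revel", "mutpred2_score",
                "spliceai_ag", "spliceai_al", "spliceai_dg", "spliceai_dl")) {
    check_range(col, 0, 1)
  }
  check_range("loeuf", 0, Inf)
  check_range("cadd_phred", 0, Inf)
  check_range("pos", 1, Inf)
  check_pair <- function(idx, total) {
    if (!all(c(idx, total) %in% names(df))) return(invisible())
    bad <- which(!is.na(df[[idx]]) & !is.na(df[[total]]) &
                   df[[idx]] > df[[total]])
    if (length(bad) > 0) {
      stop(sprintf("%s exceeds %s at row(s) %s", idx, total,
                   paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  check_pair("exon_index", "exon_total")
  check_pair("intron_index", "intron_total")
  class(df) <- unique(c("variant_table", class(df)))
  df
}

coerce_column <- function(x, type, col) {
  if (type == "character") {
    x <- as.character(x)
    x[!is.na(x) & x == ""] <- NA_character_
    return(x)
  }
  if (is.character(x)) x[x %in% c("", "NA", "na", ".")] <- NA_character_
  out <- switch(type,
    numeric = suppressWarnings(as.numeric(x)),
    integer = suppressWarnings(as.integer(as.numeric(x))),
    logical = parse_logical(x)
  )
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    stop(sprintf("non-%s value '%s' in column '%s' (row %d)",
                 type, as.character(x[bad[1]]), col, bad[1]))
  }
  out
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "yes", "1")] <- TRUE
  out[x %in% c("false", "f", "no", "0")] <- FALSE
  out
}

#' Read an annotated cohort table from TSV
#'
#' Reads the flat cohort dialect (UTF-8, tab separated, `NA` or empty cell =
#' absent) and validates it with [variant_table()]. A score cell that cannot
#' be parsed as a number is a parse error naming the row and column; a
#' missing mandatory column is a format error.
#'
#' @param path Path to a TSV file with a header row.
#' @return A `variant_table` (possibly with zero rows).
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = c("NA", ""),
                          check.names = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  variant_table(df)
}

#' Write an annotated cohort table to TSV
#'
#' Writes with a deterministic column order (dictionary columns first, in
#' dictionary order, then any extra columns alphabetically) so identical
#' inputs give byte-identical files; round-trips through
#' [read_variant_table()].
#'
#' @param df A `variant_table` or compatible data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(df, path) {
  dict <- cohort_columns()$column
  ord <- c(intersect(dict, names(df)), sort(setdiff(names(df), dict)))
  utils::write.table(df[, ord, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Classify variants into the cascade's functional classes
#'
#' Assigns each variant one of CANONICAL_SPLICE, STOP_GAIN, FRAMESHIFT,
#' MISSENSE or OTHER, in that precedence order, from its Sequence Ontology
#' consequence terms; canonical splice means a `splice_donor_variant` or
#' `splice_acceptor_variant` consequence (the invariant +-1/+-2 intronic
#' dinucleotides). When no informative term is present the protein HGVS is
#' consulted (`fs` -> frameshift, terminal `Ter`/`*` -> stop gain, a simple
#' substitution -> missense). Variants with no usable evidence are classed
#' OTHER with `class_warning = TRUE`.
#'
#' @param terms Character vector of consequence-term strings (terms
#'   separated by `&`, `,` or `;`), or a `variant_table` whose
#'   `consequence_terms`/`hgvs_p` columns are used.
#' @param hgvs_p Optional protein HGVS fallback, recycled along `terms`.
#' @return A data.frame with columns `variant_class` (factor with the levels
#'   of [variant_classes()]) and `class_warning`.
#' @export
classify_variants <- function(terms, hgvs_p = NULL) {
  if (is.data.frame(terms)) {
    hgvs_p <- terms$hgvs_p
    terms <- terms$consequence_terms
  }
  terms <- as.character(terms)
  n <- length(terms)
  if (is.null(hgvs_p)) hgvs_p <- rep(NA_character_, n)
  hgvs_p <- rep_len(as.character(hgvs_p), n)

  terms_clean <- terms
  terms_clean[is.na(terms_clean)] <- ""
  split_terms <- strsplit(terms_clean, "[&,;]\\s*")
  cls <- character(n)
  warn <- logical(n)
  for (i in seq_len(n)) {
    tm <- tolower(trimws(split_terms[[i]]))
    tm <- tm[nzchar(tm)]
    cls[i] <- if (any(tm %in% c("splice_donor_variant",
                                "splice_acceptor_variant"))) {
      "CANONICAL_SPLICE"
    } else if ("stop_gained" %in% tm) {
      "STOP_GAIN"
    } else if ("frameshift_variant" %in% tm) {
      "FRAMESHIFT"
    } else if ("missense_variant" %in% tm) {
      "MISSENSE"
    } else if (length(tm) > 0) {
      "OTHER"
    } else {
      from_p <- classify_from_hgvs_p(hgvs_p[i])
      warn[i] <- is.na(from_p)
      if (is.na(from_p)) "OTHER" else from_p
    }
  }
  data.frame(
    variant_class = factor(cls, levels = variant_classes()),
    class_warning = warn
  )
}

classify_from_hgvs_p <- function(p) {
  if (is.na(p) || !nzchar(p)) return(NA_character_)
  p <- sub("^p\\.", "", p)
  if (grepl("fs", p, ignore.case = TRUE)) return("FRAMESHIFT")
  if (grepl("(Ter|\\*)[0-9]*$", p)) return("STOP_GAIN")
  # simple substitution: Xaa<pos>Yaa, three-letter or one-letter codes
  if (grepl("^[A-Za-z]{1,3}[0-9]+[A-Za-z]{1,3}$", p)) return("MISSENSE")
  NA_character_
}

## "3/9"-style VEP EXON/INTRON strings -> c(index, total)
parse_rank_fraction <- function(x) {
  out <- matrix(NA_integer_, nrow = length(x), ncol = 2,
                dimnames = list(NULL, c("index", "total")))
  ok <- !is.na(x) & grepl("^[0-9]+/[0-9]+$", x)
  if (any(ok)) {
    parts <- do.call(rbind, strsplit(x[ok], "/", fixed = TRUE))
    out[ok, 1] <- as.integer(parts[, 1])
    out[ok, 2] <- as.integer(parts[, 2])
  }
  out
}

#' Parse a MutPred2 mechanism string
#'
#' Mechanism annotations travel as a single cell of the form
#' `"Iron binding (p=7.1352e-05); Catalytic site (p=0.0006)"`. Returns the
#' mechanisms with their prior-corrected p-values, flagging those below
#' `alpha` the way the per-variant report highlights them.
#'
#' @param x A character vector of mechanism strings (NA allowed).
#' @param alpha Highlight threshold for the prior-corrected p-values.
#' @return A data.frame with columns `mechanism`, `p`, `significant`; zero
#'   rows when nothing is annotated.
#' @export
parse_mutpred2_mechanisms <- function(x, alpha = 0.05) {
  out <- list()
  for (s in x) {
    if (is.na(s) || !nzchar(trimws(s))) next
    parts <- trimws(strsplit(s, ";")[[1]])
    parts <- parts[nzchar(parts)]
    m <- regmatches(parts, regexec(
      "^(.*?)\\s*\\(\\s*p\\s*=\\s*([0-9.eE+-]+)\\s*\\)$", parts))
    for (g in m) {
      if (length(g) == 3) {
        out[[length(out) + 1]] <- data.frame(
          mechanism = g[2], p = as.numeric(g[3]))
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(mechanism = character(), p = numeric(),
                      significant = logical()))
  }
  res <- do.call(rbind, out)
  res$significant <- res$p < alpha
  res
}
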