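#' Default gene-to-functional-category map
#'
#' Maps candidate genes to the functional categories used in family-level
#' summaries: `DNA_REPAIR_CELL_CYCLE`, `ECM_FOCAL_ADHESION`,
#' `TGFB_SIGNALING` and `OTHER`. The packaged default transcribes the
#' section assignment of the per-variant report fixture (see
#' [table2_variants()]) and is user-replaceable: any two-column
#' `gene`/`category` table works.
#'
#' @param path TSV with columns `gene` and `category`.
#' @return Named character vector: categories keyed by gene symbol.
#' @export
default_category_map <- function(path = system.file("extdata",
                                                    "category_map.tsv",
                                                    package = "varcascade")) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "category") %in% names(df)))
  stats::setNames(df$category, toupper(df$gene))
}

#' Family-level candidate counts per functional category
#'
#' Counts, per index-case family, the surviving candidate variants in each
#' functional category. Genes absent from the map count as `OTHER`;
#' variants without a family identifier are pooled under family `UNKNOWN`
#' with a warning. Category counts always sum to the family's total.
#'
#' @param variants A data.frame of (surviving) variants with `family_id`
#'   and `gene_symbol` — typically [surviving_variants()] output.
#' @param category_map Named character vector gene -> category, as
#'   [default_category_map()].
#' @return A data.frame with one row per family: one column per category
#'   (alphabetical) plus `total`.
#' @export
family_summary <- function(variants, category_map = default_category_map()) {
  fam <- as.character(variants$family_id)
  if (any(is.na(fam) | !nzchar(fam))) {
    warning("variant(s) without family_id counted under family UNKNOWN")
    fam[is.na(fam) | !nzchar(fam)] <- "UNKNOWN"
  }
  cat <- unname(category_map[toupper(as.character(variants$gene_symbol))])
  cat[is.na(cat)] <- "OTHER"
  cats <- sort(unique(c(cat, "OTHER")))
  if (length(fam) == 0) {
    out <- as.data.frame(stats::setNames(
      c(list(character(0)), rep(list(integer(0)), length(cats) + 1)),
      c("family_id", cats, "total")), check.names = FALSE)
    return(out)
  }
  tab <- table(factor(fam), factor(cat, levels = cats))
  out <- data.frame(family_id = rownames(tab), check.names = FALSE)
  for (cc in cats) out[[cc]] <- as.integer(tab[, cc])
  out$total <- as.integer(rowSums(tab))
  rownames(out) <- NULL
  out
}

#' Count families by candidate burden in a category set
#'
#' The family-level headline numbers of this kind of study have the form
#' "k families harbored at least m candidate variants in categories C".
#' This makes the category set, the threshold and the comparison mode
#' explicit parameters, and allows excluding families (e.g., a family
#' already explained by a known high-penetrance variant).
#'
#' @inheritParams family_summary
#' @param categories Character vector of category names to pool.
#' @param m Candidate-count threshold.
#' @param mode `"at_least"` (>= m) or `"exactly"` (== m).
#' @param exclude_families Families removed before counting.
#' @return A list: `n_families` (the count), `families` (their ids) and
#'   `per_family` (pooled candidate count per retained family).
#' @export
count_families_with_burden <- function(variants,
                                       categories = "DNA_REPAIR_CELL_CYCLE",
                                       m = 2L,
                                       mode = c("at_least", "exactly"),
                                       exclude_families = character(),
                                       category_map = default_category_map()) {
  mode <- match.arg(mode)
  fs <- family_summary(variants, category_map)
  fs <- fs[!fs$family_id %in% exclude_families, , drop = FALSE]
  have <- intersect(categories, names(fs))
  pooled <- if (length(have) == 0) rep(0L, nrow(fs)) else
    as.integer(rowSums(fs[, have, drop = FALSE]))
  hit <- if (mode == "at_least") pooled >= m else pooled == m
  list(n_families = sum(hit), families = fs$family_id[hit],
       per_family = stats::setNames(pooled, fs$family_id))
}

#' Genes with candidate variants in more than one family
#'
#' @param variants A data.frame of variants with `gene_symbol`,
#'   `family_id` and `variant_id`.
#' @return A data.frame of genes hit in >= 2 distinct families:
#'   `gene_symbol`, `n_families`, `families` and `variant_ids`
#'   (semicolon-joined); zero rows when there is no recurrence.
#' @export
recurrent_genes <- function(variants) {
  if (nrow(variants) == 0) {
    return(data.frame(gene_symbol = character(), n_families = integer(),
                      families = character(), variant_ids = character()))
  }
  sp <- split(variants, toupper(as.character(variants$gene_symbol)))
  rows <- lapply(names(sp), function(g) {
    fams <- sort(unique(as.character(sp[[g]]$family_id)))
    if (length(fams) < 2) return(NULL)
    data.frame(gene_symbol = g, n_families = length(fams),
               families = paste(fams, collapse = ";"),
               variant_ids = paste(sort(sp[[g]]$variant_id),
                                   collapse = ";"))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    return(data.frame(gene_symbol = character(), n_families = integer(),
                      families = character(), variant_ids = character()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_symbol), ]
  rownames(out) <- NULL
  out
}

#' Run the full prioritization pipeline end to end
#'
#' Reads an annotated cohort, runs the filtering cascade, builds the PPI
#' network over surviving genes plus the seed predisposition genes,
#' extracts connected components, Markov-clusters the network, tests each
#' cluster for gene-set enrichment, and writes the report bundle:
#' `variants.tsv` (prioritized variants), `network_edges.tsv`,
#' `clusters.tsv`, `enrichment.tsv`, `family_summary.tsv` and
#' `manifest.json` (effective configuration, input checksums, package
#' version, seed). On any stage error the partially written bundle is
#' removed and the error is re-raised with the stage name.
#'
#' @param cohort_path Cohort TSV (see [read_variant_table()]).
#' @param edges_path STRING-export edge TSV (see [read_string_edges()]).
#' @param gmt_paths Character vector of GMT files.
#' @param seeds_path Seed gene list (one symbol per line); `NULL` for none.
#' @param out_dir Output directory (created if needed).
#' @param config A [threshold_config()] or named list of overrides.
#' @param category_map See [family_summary()].
#' @param seed RNG seed for the permutation PPI enrichment p-value.
#' @param n_perm Permutations for the PPI enrichment p-value.
#' @return Invisibly, a list with the in-memory results: `cascade`, `net`,
#'   `components`, `clusters`, `enrichment`, `families`, `recurrent`,
#'   `ppi_p`, `manifest`.
#' @export
run_pipeline <- function(cohort_path, edges_path, gmt_paths = character(),
                         seeds_path = NULL, out_dir = ".", config = NULL,
                         category_map = default_category_map(),
                         seed = 1L, n_perm = 2000L) {
  for (f in c(cohort_path, edges_path, gmt_paths,
              if (!is.null(seeds_path)) seeds_path)) {
    if (!file.exists(f)) stop("input file not found: ", f)
  }
  t <- as_threshold_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  stage <- "setup"
  res <- tryCatch({
    stage <- "cascade"
    cohort <- read_variant_table(cohort_path)
    casc <- run_cascade(cohort, t)
    f <- file.path(out_dir, "variants.tsv")
    write_report(casc, f)
    written <- c(written, f)

    stage <- "network"
    surv <- surviving_variants(casc)
    seeds <- if (is.null(seeds_path)) character() else
      read_seed_genes(seeds_path)
    edges <- read_string_edges(edges_path)
    net <- build_network(edges, unique(surv$gene_symbol), seeds, t)
    comp <- network_components(net)
    f <- file.path(out_dir, "network_edges.tsv")
    utils::write.table(net$edges, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, f)
    ppi_p <- if (nrow(edges) > 0 &&
                 all(net$nodes %in% c(edges$protein_a, edges$protein_b))) {
      ppi_enrichment_pvalue(net, edges, method = "permutation",
                            n_perm = n_perm, seed = seed)
    } else NULL

    stage <- "clustering"
    cl <- mcl_cluster(net, inflation = t$mcl_inflation,
                      expansion = t$mcl_expansion,
                      max_iter = t$mcl_max_iter, tol = t$mcl_tol)
    f <- file.path(out_dir, "clusters.tsv")
    utils::write.table(
      data.frame(node = names(cl$membership),
                 cluster = unname(cl$membership)),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)

    stage <- "enrichment"
    enr <- if (length(gmt_paths) > 0) {
      sets <- read_gmt(gmt_paths)
      enrich_clusters(cl, sets, alpha = t$fdr_alpha)
    } else NULL
    if (!is.null(enr)) {
      f <- file.path(out_dir, "enrichment.tsv")
      utils::write.table(enr, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <- c(written, f)
    }

    stage <- "report"
    fams <- family_summary(surv, category_map)
    f <- file.path(out_dir, "family_summary.tsv")
    utils::write.table(fams, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, f)
    rec <- recurrent_genes(surv)

    inputs <- c(cohort_path, edges_path, gmt_paths,
                if (!is.null(seeds_path)) seeds_path)
    manifest <- list(
      package = "varcascade",
      version = as.character(utils::packageVersion("varcascade")),
      config = unclass(t),
      inputs = as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                       basename(inputs))),
      seed = seed, n_perm = n_perm,
      n_variants = nrow(cohort$variants %||% cohort),
      n_survivors = nrow(surv),
      n_connected = comp$n_connected,
      ppi_enrichment_p = if (is.null(ppi_p)) NA else ppi_p$p)
    f <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <- c(written, f)

    list(cascade = casc, net = net, components = comp, clusters = cl,
         enrichment = enr, families = fams, recurrent = rec,
         ppi_p = ppi_p, manifest = manifest)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
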