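# Shared helpers: tiny in-code fixtures and independent oracles.

# minimal cohort rows with every mandatory column and sensible defaults
toy_variant <- function(variant_id = "1_100_A_T", family_id = "F1",
                        gene_symbol = "GENE1",
                        consequence_terms = "missense_variant", ...) {
  base <- data.frame(variant_id = variant_id, family_id = family_id,
                     gene_symbol = gene_symbol,
                     consequence_terms = consequence_terms,
                     stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) base[[nm]] <- extra[[nm]]
  base
}

# rbind data.frames with unequal columns, filling the gaps with NA
rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (nm in setdiff(cols, names(d))) d[[nm]] <- NA
    d[cols]
  }))
}

# a cohort guaranteed to survive all gates for its class
surviving_missense <- function(variant_id = "1_100_A_T", family_id = "F1",
                               gene_symbol = "GENE1") {
  calls <- as.list(stats::setNames(rep("deleterious", 9),
                                   paste0("call_", predictor_tools())))
  do.call(toy_variant, c(list(variant_id = variant_id,
                              family_id = family_id,
                              gene_symbol = gene_symbol,
                              consequence_terms = "missense_variant",
                              cadd_phred = 30, gerp = 5, phastcons = 0.9,
                              phylop = 6),
                         calls))
}

# two 4-cliques joined by a single weak bridge; the canonical MCL testbed
two_clique_edges <- function(w_clique = 1.0, w_bridge = 0.1) {
  cl <- function(nodes, w) {
    pairs <- t(utils::combn(nodes, 2))
    data.frame(protein_a = pairs[, 1], protein_b = pairs[, 2],
               combined_score = w, stringsAsFactors = FALSE)
  }
  a <- paste0("A", 1:4)
  b <- paste0("B", 1:4)
  rbind(cl(a, w_clique), cl(b, w_clique),
        data.frame(protein_a = "A1", protein_b = "B1",
                   combined_score = w_bridge))
}

# exhaustive hypergeometric upper tail by enumerating all C(N, n) draws
hyper_tail_enum <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  in_term <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% in_term))
  mean(hits >= k)
}

# textbook BH step-up applied literally
bh_stepup <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, m * p[ord[i]] / i)
    q[ord[i]] <- prev
  }
  pmin(q, 1)
}
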