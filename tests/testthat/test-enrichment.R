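test_that("hypergeometric upper tail matches exhaustive enumeration", {
  # perfect overlap of a 5-gene query with a 5-gene term in a 10-gene urn
  expect_equal(hypergeom_upper_tail(5, 5, 5, 10), 1 / 252)
  expect_equal(hypergeom_upper_tail(0, 5, 5, 10), 1)
  # enumeration oracle over all C(N, n) draws for small urns
  cases <- list(c(2, 5, 4, 10), c(3, 6, 5, 12), c(1, 3, 7, 11),
                c(4, 4, 4, 8))
  for (cs in cases) {
    expect_equal(hypergeom_upper_tail(cs[1], cs[2], cs[3], cs[4]),
                 hyper_tail_enum(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12)
  }
  # cross-check against the distribution function on a larger urn
  expect_equal(hypergeom_upper_tail(6, 10, 20, 100),
               stats::phyper(5, 10, 90, 20, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(hypergeom_upper_tail(6, 5, 5, 10), "exceeds")
})

test_that("upper tail is non-increasing in the observed overlap", {
  p <- vapply(0:10, hypergeom_upper_tail, numeric(1), K = 10, n = 20,
              N = 100)
  expect_true(all(diff(p) <= 0))
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(99)
  for (i in 1:1000) {
    p <- stats::runif(sample(1:20, 1))
    expect_equal(bh_fdr(p), bh_stepup(p))
  }
  # agreement with the standard implementation, order preserved
  set.seed(5)
  p <- stats::runif(50)
  expect_equal(bh_fdr(p), stats::p.adjust(p, method = "BH"))
  expect_error(bh_fdr(c(0.1, 1.4)), "outside")
})

test_that("cluster enrichment composes the tail test with per-collection BH", {
  bg <- sprintf("G%03d", 1:100)
  sets <- gene_set_collection(
    data.frame(term_id = "T1", term_name = "term one",
               collection = "go_bp"),
    list(T1 = bg[1:10]), background = bg)
  res <- enrich_clusters(list(cl1 = bg[1:5]), sets)
  expect_equal(res$k, 5)
  expect_equal(res$p, hypergeom_upper_tail(5, 10, 5, 100))
  expect_equal(res$q, res$p)  # single term: BH is the identity
  # disjoint cluster yields no rows
  expect_equal(nrow(enrich_clusters(list(x = bg[50:60]), sets)), 0)
  # BH is applied within each collection separately
  sets2 <- gene_set_collection(
    data.frame(term_id = c("T1", "T2", "K1"),
               term_name = c("a", "b", "c"),
               collection = c("go_bp", "go_bp", "kegg")),
    list(T1 = bg[1:10], T2 = bg[1:50], K1 = bg[1:10]), background = bg)
  res2 <- enrich_clusters(list(cl1 = bg[1:5]), sets2)
  go <- res2[res2$collection == "go_bp", ]
  expect_equal(sort(go$q), sort(bh_fdr(go$p)))
  expect_equal(res2$q[res2$collection == "kegg"],
               res2$p[res2$collection == "kegg"])
})

test_that("planted enriched terms beat decoys on the generated benchmark", {
  wins <- vapply(1:20, function(s) {
    sim <- generate_network_and_sets(network_sim_config(
      n_modules = 3, module_size = 8, seed = 2000 + s))
    res <- enrich_clusters(list(q = names(sim$membership)[sim$membership == 1]),
                           sim$sets)
    res$term_id[which.min(res$q)] == "MODULE_01"
  }, logical(1))
  expect_gt(mean(wins), 0.95)
})

test_that("PPI enrichment p-value behaves under both nulls", {
  set.seed(17)
  # sparse background with a planted 6-clique
  bg_nodes <- sprintf("N%03d", 1:200)
  m <- 300
  bg <- data.frame(protein_a = sample(bg_nodes, m, TRUE),
                   protein_b = sample(bg_nodes, m, TRUE))
  bg <- bg[bg$protein_a != bg$protein_b, ]
  clique <- t(utils::combn(sprintf("N%03d", 1:6), 2))
  bg <- rbind(bg, data.frame(protein_a = clique[, 1],
                             protein_b = clique[, 2]))
  p_perm <- ppi_enrichment_pvalue(sprintf("N%03d", 1:6), bg,
                                  method = "permutation", n_perm = 10000,
                                  seed = 4)
  expect_lte(p_perm$p, 0.01)
  p_pois <- ppi_enrichment_pvalue(sprintf("N%03d", 1:6), bg,
                                  method = "poisson_approx")
  expect_lt(p_pois$p, 0.01)
  # the two nulls agree within an order of magnitude on a moderate signal,
  # where the permutation estimator is not saturated at 1/(n_perm + 1)
  q_mod <- c(sprintf("N%03d", 1:3), sprintf("N%03d", 101:107))
  pm <- ppi_enrichment_pvalue(q_mod, bg, "permutation", 10000, 4)
  po <- ppi_enrichment_pvalue(q_mod, bg, "poisson_approx")
  expect_lt(abs(log10(pm$p) - log10(po$p)), 1)
  # no observed edges -> p = 1 in both modes
  iso <- build_network(bg[0, ], candidates = c("N001", "N050"))
  expect_equal(ppi_enrichment_pvalue(iso, bg, "permutation", 100, 1)$p, 1,
               tolerance = 0.02)
  expect_equal(ppi_enrichment_pvalue(iso, bg, "poisson_approx")$p, 1)
  expect_error(ppi_enrichment_pvalue(c("N001", "NOPE"), bg,
                                     "poisson_approx"),
               "absent from background")
})

test_that("permutation p-values are super-uniform under null resampling", {
  set.seed(23)
  bg_nodes <- sprintf("N%02d", 1:80)
  bg <- data.frame(protein_a = sample(bg_nodes, 150, TRUE),
                   protein_b = sample(bg_nodes, 150, TRUE))
  bg <- bg[bg$protein_a != bg$protein_b, ]
  universe <- unique(c(bg$protein_a, bg$protein_b))
  pvals <- vapply(1:100, function(r) {
    q <- sample(universe, 8)
    ppi_enrichment_pvalue(q, bg, method = "permutation", n_perm = 2000,
                          seed = 3000 + r)$p
  }, numeric(1))
  for (alpha in c(0.05, 0.1, 0.25, 0.5)) {
    # binomial slack: 3 SD above alpha at 100 replicates
    slack <- 3 * sqrt(alpha * (1 - alpha) / 100)
    expect_lte(mean(pvals <= alpha), alpha + slack)
  }
})
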