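test_that("channel combination honors the prior-strip identities", {
  # single nonzero channel: strip then re-add is the identity
  expect_equal(combine_channel_scores(c(0.7, 0, 0)), 0.7)
  expect_equal(combine_channel_scores(c(0, 0.7, 0)), 0.7)
  # all-zero channels floor at the prior
  expect_equal(combine_channel_scores(c(0, 0, 0)), 0.041)
  # closed-form spreadsheet-style evaluation for two active channels
  p <- 0.041
  s <- (0.7 - p) / (1 - p)
  expected <- (1 - (1 - s)^2) * (1 - p) + p
  expect_equal(combine_channel_scores(c(0.7, 0.7, 0)), expected)
  # permutation symmetry and bounds
  set.seed(1)
  for (i in 1:20) {
    ch <- stats::runif(3)
    expect_equal(combine_channel_scores(ch),
                 combine_channel_scores(sample(ch)))
    expect_gte(combine_channel_scores(ch), 0.041)
    expect_lte(combine_channel_scores(ch), 1)
  }
  # monotone non-decreasing in every channel
  base <- combine_channel_scores(c(0.3, 0.5, 0.2))
  expect_gte(combine_channel_scores(c(0.4, 0.5, 0.2)), base)
  expect_gte(combine_channel_scores(c(0.3, 0.6, 0.2)), base)
  expect_gte(combine_channel_scores(c(0.3, 0.5, 0.3)), base)
  expect_error(combine_channel_scores(c(1.2, 0, 0)), "outside")
})

test_that("network construction applies the inclusive 0.400 threshold", {
  edges <- data.frame(protein_a = c("A", "A", "B"),
                      protein_b = c("B", "C", "C"),
                      combined_score = c(0.400, 0.399, 0.9))
  net <- build_network(edges, candidates = c("A", "B", "C"))
  expect_equal(nrow(net$edges), 2)         # 0.399 dropped, 0.400 kept
  expect_equal(net$dropped_low_score, 1)
  # unknown symbols are dropped with a count, not an error
  edges2 <- rbind(edges, data.frame(protein_a = "A", protein_b = "ZZZ",
                                    combined_score = 0.9))
  net2 <- build_network(edges2, candidates = c("A", "B", "C"))
  expect_equal(net2$dropped_unknown, 1)
  # empty edge list still yields the full node set
  net3 <- build_network(edges[0, ], candidates = c("a", "b"))
  expect_equal(net3$nodes, c("A", "B"))    # case-normalized
  expect_equal(nrow(net3$edges), 0)
  # channel columns are recombined rather than trusted
  chan <- data.frame(protein_a = "A", protein_b = "B",
                     experiments = 0.7, database = 0, coexpression = 0)
  net4 <- build_network(chan, candidates = c("A", "B"))
  expect_equal(net4$edges$combined_score, 0.7)
})

test_that("edge survival is monotone non-increasing in the score threshold", {
  set.seed(3)
  edges <- data.frame(protein_a = sample(LETTERS[1:8], 40, TRUE),
                      protein_b = sample(LETTERS[1:8], 40, TRUE),
                      combined_score = round(stats::runif(40), 3))
  edges <- edges[edges$protein_a != edges$protein_b, ]
  counts <- vapply(seq(0, 1, by = 0.1), function(th) {
    nrow(build_network(edges, LETTERS[1:8],
                       config = list(string_min_score = th))$edges)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("components separate modules and count connected proteins", {
  tri <- function(nodes) {
    p <- t(utils::combn(nodes, 2))
    data.frame(protein_a = p[, 1], protein_b = p[, 2], combined_score = 0.9)
  }
  edges <- rbind(tri(c("A1", "A2", "A3")), tri(c("B1", "B2", "B3")))
  net <- build_network(edges, candidates = c(paste0("A", 1:3),
                                             paste0("B", 1:3), "LONER"))
  comp <- network_components(net)
  expect_equal(length(comp$components), 2)
  expect_equal(sort(vapply(comp$components, length, integer(1))), c(3L, 3L))
  expect_equal(comp$n_connected, 6)
  expect_equal(comp$isolated, "LONER")
  # empty graph
  empty <- build_network(edges[0, ], candidates = c("X", "Y"))
  ec <- network_components(empty)
  expect_equal(length(ec$components), 0)
  expect_equal(ec$n_connected, 0)
})

test_that("MCL resolves two bridged 4-cliques into exactly the cliques", {
  net <- build_network(two_clique_edges(), candidates = c(paste0("A", 1:4),
                                                          paste0("B", 1:4)),
                       config = list(string_min_score = 0.05))
  cl <- mcl_cluster(net, inflation = 2)
  expect_true(cl$converged)
  got <- lapply(cl$clusters, sort)
  expect_true(list(paste0("A", 1:4)) %in% got ||
                identical(got[[1]], paste0("A", 1:4)) ||
                identical(got[[2]], paste0("A", 1:4)))
  expect_setequal(vapply(got, paste, character(1), collapse = ","),
                  c("A1,A2,A3,A4", "B1,B2,B3,B4"))
})

test_that("MCL output refines connected components and handles degenerates", {
  tri <- function(nodes) {
    p <- t(utils::combn(nodes, 2))
    data.frame(protein_a = p[, 1], protein_b = p[, 2], combined_score = 0.9)
  }
  edges <- rbind(tri(c("A1", "A2", "A3")), tri(c("B1", "B2", "B3")))
  net <- build_network(edges, candidates = c(paste0("A", 1:3),
                                             paste0("B", 1:3)))
  cl <- mcl_cluster(net)
  comp <- igraph::components(net$graph)$membership
  for (cluster in cl$clusters) {
    expect_equal(length(unique(comp[cluster])), 1)  # never spans components
  }
  # single node with a self-loop -> one singleton cluster
  single <- matrix(1, 1, 1, dimnames = list("X", "X"))
  expect_equal(mcl_cluster(single)$clusters, list("X"))
  # idempotence on clique inputs: re-clustering a recovered clique keeps it
  a_sub <- build_network(two_clique_edges()[1:6, ], candidates = paste0("A", 1:4),
                         config = list(string_min_score = 0.05))
  expect_equal(mcl_cluster(a_sub, inflation = 2)$clusters,
               list(paste0("A", 1:4)))
})

test_that("MCL recovers planted partitions with high agreement", {
  skip_if_not_installed("mclust")
  agreements <- vapply(1:10, function(s) {
    sim <- generate_network_and_sets(network_sim_config(
      n_modules = 4, module_size = 10, seed = 1000 + s))
    net <- build_network(sim$edges, candidates = sim$genes)
    cl <- mcl_cluster(net)
    mclust::adjustedRandIndex(cl$membership[sim$genes],
                              sim$membership[sim$genes])
  }, numeric(1))
  expect_gt(mean(agreements), 0.9)
})
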