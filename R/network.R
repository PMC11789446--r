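#' Combine STRING-style channel scores under the random-interaction prior
#'
#' STRING's combined edge confidence strips the shared random-interaction
#' prior `p` from every evidence channel, combines the stripped scores as
#' independent probabilities, and re-adds the prior: with
#' `s' = max(0, (s - p) / (1 - p))` per channel, the combined score is
#' `(1 - prod(1 - s')) * (1 - p) + p`. The result is symmetric in the
#' channels, equals a channel's value when the other channels are zero,
#' never falls below the prior and never exceeds 1.
#'
#' @param channels A numeric vector of channel scores in `[0, 1]` (one
#'   edge), or a matrix / data.frame with one column per channel (one row
#'   per edge).
#' @param prior Random-interaction prior in `[0, 1)`; STRING documents
#'   0.041.
#' @return Numeric vector of combined scores, one per edge.
#' @examples
#' combine_channel_scores(c(0.7, 0, 0))        # 0.7
#' combine_channel_scores(c(0, 0, 0))          # the prior floor, 0.041
#' @export
combine_channel_scores <- function(channels, prior = 0.041) {
  stopifnot(prior >= 0, prior < 1)
  if (is.data.frame(channels)) channels <- as.matrix(channels)
  if (!is.matrix(channels)) channels <- matrix(channels, nrow = 1)
  if (any(channels < 0 | channels > 1, na.rm = TRUE)) {
    stop("channel score outside [0, 1]")
  }
  channels[is.na(channels)] <- 0
  stripped <- matrix(pmax(0, (channels - prior) / (1 - prior)),
                     nrow = nrow(channels))
  combined <- 1 - apply(1 - stripped, 1, prod)
  combined * (1 - prior) + prior
}

#' Read a STRING-export interaction edge list
#'
#' Accepts the tab-separated layout of STRING's interaction export:
#' two endpoint columns (`node1`/`node2`, `protein1`/`protein2`, or the
#' `#node1` variant) and any of the evidence channel columns used here
#' (`experiments`/`experimentally_determined_interaction`,
#' `database`/`database_annotated`, `coexpression`) plus `combined_score`.
#' Scores on the 0-1000 integer scale are detected and normalized to
#' `[0, 1]`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `protein_a`, `protein_b`, any of
#'   `experiments`, `database`, `coexpression`, and `combined_score` when
#'   present.
#' @export
read_string_edges <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "",
                          na.strings = c("NA", ""))
  names(df) <- sub("^#", "", tolower(names(df)))
  pick <- function(cands) {
    hit <- intersect(cands, names(df))
    if (length(hit) == 0) NULL else df[[hit[1]]]
  }
  a <- pick(c("node1", "protein1", "protein_a"))
  b <- pick(c("node2", "protein2", "protein_b"))
  if (is.null(a) || is.null(b)) {
    stop("edge list must carry two endpoint columns (node1/node2)")
  }
  out <- data.frame(protein_a = toupper(as.character(a)),
                    protein_b = toupper(as.character(b)),
                    stringsAsFactors = FALSE)
  chan_map <- list(
    experiments = c("experiments", "experimentally_determined_interaction",
                    "experimental"),
    database = c("database", "database_annotated", "databases"),
    coexpression = c("coexpression"),
    combined_score = c("combined_score", "score")
  )
  for (nm in names(chan_map)) {
    v <- pick(chan_map[[nm]])
    if (!is.null(v)) {
      v <- as.numeric(v)
      if (any(v > 1, na.rm = TRUE)) v <- v / 1000  # STRING integer scale
      out[[nm]] <- v
    }
  }
  out
}

#' Read a seed gene list
#'
#' One gene symbol per line; blank lines and `#` comments ignored; symbols
#' upper-cased and deduplicated.
#'
#' @param path Path to a plain-text file.
#' @return Character vector of symbols.
#' @export
read_seed_genes <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  unique(toupper(x[nzchar(x)]))
}

#' Build the candidate + seed protein-protein interaction network
#'
#' The node set is the union of the candidate genes (the cascade survivors)
#' and the seed list of known predisposition genes, case-normalized to
#' upper case. Edges are kept when both endpoints are in the node set and
#' the combined score reaches `string_min_score` (inclusive, a "minimum
#' required" score). When the edge table carries evidence channel columns,
#' the combined score is recomputed from the active channels under the
#' configured prior; otherwise a provided `combined_score` is used as-is.
#' Duplicate unordered pairs keep their maximum score; self-edges and edges
#' touching unknown symbols are dropped with a count.
#'
#' @param edges An edge data.frame as returned by [read_string_edges()].
#' @param candidates Character vector of candidate gene symbols.
#' @param seeds Character vector of seed gene symbols.
#' @param config A [threshold_config()]; `string_min_score` and
#'   `string_prior` are used.
#' @param channels Channel columns treated as active interaction sources.
#' @return A `ppi_network`: list with `graph` (weighted undirected
#'   [igraph::graph]), `nodes`, `edges` (the retained table),
#'   `dropped_unknown`, `dropped_low_score`.
#' @export
build_network <- function(edges, candidates, seeds = character(),
                          config = NULL,
                          channels = c("experiments", "database",
                                       "coexpression")) {
  t <- as_threshold_config(config)
  nodes <- unique(toupper(c(candidates, seeds)))
  stopifnot(length(nodes) > 0)
  e <- edges
  e$protein_a <- toupper(as.character(e$protein_a))
  e$protein_b <- toupper(as.character(e$protein_b))
  known <- e$protein_a %in% nodes & e$protein_b %in% nodes &
    e$protein_a != e$protein_b
  dropped_unknown <- sum(!known)
  e <- e[known, , drop = FALSE]

  chan_cols <- intersect(channels, names(e))
  if (nrow(e) == 0) {
    e$combined_score <- numeric(0)
  } else if (length(chan_cols) > 0) {
    e$combined_score <- combine_channel_scores(e[, chan_cols, drop = FALSE],
                                               t$string_prior)
  } else if (!"combined_score" %in% names(e)) {
    stop("edge table has neither channel columns nor combined_score")
  }

  # canonical unordered pairs; duplicates keep the maximum combined score
  if (nrow(e) > 0) {
    swap <- e$protein_a > e$protein_b
    tmp <- e$protein_a[swap]
    e$protein_a[swap] <- e$protein_b[swap]
    e$protein_b[swap] <- tmp
    key <- paste(e$protein_a, e$protein_b, sep = "|")
    e <- e[order(key, -e$combined_score), , drop = FALSE]
    e <- e[!duplicated(paste(e$protein_a, e$protein_b, sep = "|")), ,
           drop = FALSE]
  }
  keep <- e$combined_score >= t$string_min_score
  dropped_low <- sum(!keep)
  e <- e[keep, , drop = FALSE]
  rownames(e) <- NULL

  g <- igraph::graph_from_data_frame(
    d = if (nrow(e) > 0) {
      data.frame(from = e$protein_a, to = e$protein_b,
                 weight = e$combined_score)
    } else {
      data.frame(from = character(), to = character(), weight = numeric())
    },
    directed = FALSE,
    vertices = data.frame(name = sort(nodes)))
  structure(list(graph = g, nodes = sort(nodes), edges = e,
                 dropped_unknown = dropped_unknown,
                 dropped_low_score = dropped_low),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges (%d connected nodes)\n",
              length(x$nodes), nrow(x$edges),
              network_components(x)$n_connected))
  invisible(x)
}

#' Connected components of a PPI network
#'
#' Components in the graph-theoretic sense, with isolated nodes (degree 0)
#' reported separately — network figures of this kind show only connected
#' nodes, and the count of proteins interacting with at least one other
#' protein is a headline quantity of the analysis.
#'
#' @param net A `ppi_network` from [build_network()].
#' @return A list: `components` (list of node-name vectors, largest first),
#'   `n_connected` (nodes with degree >= 1), `isolated` (node names).
#' @export
network_components <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  g <- net$graph
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  membership <- comp$membership
  groups <- split(names(membership), membership)
  groups <- groups[vapply(groups, length, integer(1)) > 1]
  groups <- groups[order(-vapply(groups, length, integer(1)),
                         vapply(groups, function(x) sort(x)[1],
                                character(1)))]
  list(components = unname(groups),
       n_connected = sum(deg >= 1),
       isolated = names(deg)[deg == 0])
}

#' Markov clustering (MCL) of a weighted network
#'
#' Clusters the combined-score weighted adjacency matrix by the Markov
#' Cluster algorithm: add self-loops (weight = the node's maximum incident
#' edge weight, or 1 for isolated nodes), column-normalize into a column
#' stochastic flow matrix, then alternate expansion (matrix power) and
#' inflation (elementwise power followed by column renormalization) until
#' the flow changes by less than `tol` or `max_iter` is reached. Clusters
#' are read from the attractor rows of the limit matrix; a node attracted
#' by several attractors is assigned to the lowest-index one, making the
#' partition deterministic for a fixed node order. Every cluster lies
#' within one connected component.
#'
#' @param net A `ppi_network`, or a square weighted adjacency matrix with
#'   dimnames.
#' @param inflation Inflation exponent (> 1); larger values give finer
#'   clusters. Default 3, matching the STRING web default granularity.
#' @param expansion Expansion power (integer >= 2).
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the maximum absolute change of the
#'   flow matrix.
#' @return A `cluster_assignment`: list with `membership` (named integer
#'   vector, cluster ids 1..k ordered by cluster size then first member),
#'   `clusters` (list of node-name vectors), `converged`, `iterations`,
#'   `parameters`.
#' @export
mcl_cluster <- function(net, inflation = 3.0, expansion = 2L,
                        max_iter = 100L, tol = 1e-6) {
  stopifnot(inflation > 1, expansion >= 2)
  if (inherits(net, "ppi_network")) {
    adj <- as.matrix(igraph::as_adjacency_matrix(net$graph,
                                                 attr = "weight",
                                                 sparse = TRUE))
  } else {
    adj <- as.matrix(net)
    stopifnot(nrow(adj) == ncol(adj), !is.null(rownames(adj)))
  }
  nodes <- rownames(adj)
  n <- nrow(adj)
  if (n == 0) {
    return(structure(list(membership = stats::setNames(integer(0),
                                                       character(0)),
                          clusters = list(), converged = TRUE,
                          iterations = 0L,
                          parameters = list(inflation = inflation,
                                            expansion = expansion)),
                     class = "cluster_assignment"))
  }
  loop <- apply(adj, 1, max)
  loop[loop <= 0] <- 1
  diag(adj) <- loop
  M <- sweep(adj, 2, colSums(adj), "/")
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M_new <- M
    for (k in seq_len(expansion - 1L)) M_new <- M_new %*% M
    M_new <- M_new ^ inflation
    M_new[M_new < 1e-12] <- 0
    cs <- colSums(M_new)
    cs[cs == 0] <- 1
    M_new <- sweep(M_new, 2, cs, "/")
    delta <- max(abs(M_new - M))
    M <- M_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge in ", max_iter, " iterations")
  }
  # attractors: rows with positive mass; members: columns they attract
  attractors <- which(rowSums(M) > 1e-8)
  membership <- rep(NA_integer_, n)
  for (a in attractors) {
    cols <- which(M[a, ] > 1e-8)
    take <- cols[is.na(membership[cols])]  # lowest-index attractor wins
    membership[take] <- a
  }
  membership[is.na(membership)] <- which(is.na(membership))  # safety net
  ids <- relabel_clusters(membership, nodes)
  clusters <- split(nodes, ids)
  clusters <- clusters[order(as.integer(names(clusters)))]
  structure(list(
    membership = stats::setNames(ids, nodes),
    clusters = unname(clusters),
    converged = converged, iterations = it,
    parameters = list(inflation = inflation, expansion = expansion,
                      max_iter = max_iter, tol = tol)),
    class = "cluster_assignment")
}

relabel_clusters <- function(membership, nodes) {
  sizes <- table(membership)
  first <- tapply(seq_along(membership), membership, min)
  ord <- order(-as.integer(sizes[names(first)]), as.integer(first))
  lab <- stats::setNames(seq_along(ord), names(first)[ord])
  as.integer(lab[as.character(membership)])
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d nodes in %d clusters\n",
              length(x$membership), length(x$clusters)))
  sizes <- vapply(x$clusters, length, integer(1))
  cat("  sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}
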