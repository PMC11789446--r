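#' Read gene-set collections from GMT files
#'
#' Standard GMT: one set per line, `term_id <TAB> term_name <TAB> gene ...`.
#' Several files can be read into one collection object, each under its own
#' collection label (GO BP, KEGG, Reactome, ...), because false-discovery
#' control is applied within a collection.
#'
#' @param paths Character vector of GMT file paths.
#' @param collections Labels, one per path; defaults to the file base names.
#' @return A `gene_set_collection`: list with `terms` (data.frame
#'   `term_id`, `term_name`, `collection`), `members` (named list of gene
#'   symbol vectors keyed by `term_id`) and `background` (union of all
#'   members).
#' @export
read_gmt <- function(paths, collections = NULL) {
  if (is.null(collections)) {
    collections <- sub("\\.gmt$", "", basename(paths))
  }
  stopifnot(length(collections) == length(paths))
  terms <- list()
  members <- list()
  for (i in seq_along(paths)) {
    for (ln in readLines(paths[i], warn = FALSE)) {
      if (!nzchar(trimws(ln))) next
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 3) {
        stop("malformed GMT line in ", paths[i], ": ", substr(ln, 1, 60))
      }
      id <- parts[1]
      if (id %in% names(members)) stop("duplicate term_id: ", id)
      terms[[length(terms) + 1]] <- data.frame(
        term_id = id, term_name = parts[2], collection = collections[i])
      members[[id]] <- unique(toupper(parts[-(1:2)]))
    }
  }
  gene_set_collection(do.call(rbind, terms), members)
}

#' Construct a gene-set collection from in-memory pieces
#'
#' @param terms Data.frame with `term_id`, `term_name`, `collection`.
#' @param members Named list of gene vectors keyed by `term_id`.
#' @param background Optional gene universe; defaults to the union of all
#'   members. Members are restricted to the background.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(terms, members, background = NULL) {
  stopifnot(is.data.frame(terms),
            all(c("term_id", "term_name", "collection") %in% names(terms)),
            !anyDuplicated(terms$term_id),
            all(terms$term_id %in% names(members)))
  members <- lapply(members, function(g) unique(toupper(g)))
  if (is.null(background)) {
    background <- sort(unique(unlist(members, use.names = FALSE)))
  } else {
    background <- sort(unique(toupper(background)))
    members <- lapply(members, intersect, y = background)
  }
  if (length(background) == 0) stop("empty background universe")
  structure(list(terms = terms, members = members, background = background),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d terms in %d collection(s), %d background genes\n",
              nrow(x$terms), length(unique(x$terms$collection)),
              length(x$background)))
  invisible(x)
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability that a
#' query of `n` genes drawn from a background of `N` overlaps an annotation
#' term of `K` genes in at least `k` members. Computed by direct summation
#' of the exact probability mass in log space, so small tail probabilities
#' do not underflow.
#'
#' @param k Observed overlap.
#' @param K Term size within the background.
#' @param n Query size.
#' @param N Background size.
#' @return The upper-tail probability; `1` when `k <= 0`.
#' @examples
#' hypergeom_upper_tail(5, 5, 5, 10)  # 1/252
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1,
            K >= 0, n >= 0, N >= 0, K <= N, n <= N)
  if (k > min(K, n)) stop("overlap k exceeds min(K, n)")
  if (k <= 0) return(1)
  j <- seq(k, min(K, n))
  j <- j[n - j <= N - K]
  if (length(j) == 0) return(0)
  logp <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  m <- max(logp)
  min(1, exp(m + log(sum(exp(logp - m)))))
}

#' Benjamini-Hochberg adjusted values
#'
#' The step-up FDR procedure: with sorted p-values `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1, returned in the input
#' order. `NA` p-values propagate as `NA` and do not count toward `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-value outside [0, 1]")
  ok <- !is.na(p)
  m <- sum(ok)
  q <- rep(NA_real_, length(p))
  if (m == 0) return(q)
  ord <- order(p[ok])
  ps <- p[ok][ord]
  qs <- pmin(1, m * ps / seq_len(m))
  qs <- rev(cummin(rev(qs)))
  tmp <- q[ok]
  tmp[ord] <- qs
  q[ok] <- tmp
  q
}

#' Hypergeometric enrichment of network clusters
#'
#' For each cluster and each annotation term sharing at least one gene, the
#' overlap is tested with [hypergeom_upper_tail()] against the collection's
#' background universe, and Benjamini-Hochberg adjustment is applied per
#' cluster within each collection (GO BP, KEGG and Reactome FDRs are
#' controlled separately, matching how per-category enrichment is usually
#' reported). Query genes outside the background are ignored for the test.
#'
#' @param clusters A `cluster_assignment` from [mcl_cluster()], a named
#'   list of gene vectors, or a single character vector (treated as one
#'   cluster).
#' @param sets A `gene_set_collection`.
#' @param alpha Significance level recorded in the `significant` column.
#' @return A data.frame with one row per (cluster, term) with `k > 0`:
#'   `cluster`, `collection`, `term_id`, `term_name`, `k`, `K`, `n`, `N`,
#'   `p`, `q`, `significant`; sorted by cluster, then `q`, then `term_id`.
#' @export
enrich_clusters <- function(clusters, sets, alpha = 0.05) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (inherits(clusters, "cluster_assignment")) {
    cl <- clusters$clusters
    names(cl) <- seq_along(cl)
  } else if (is.character(clusters)) {
    cl <- list(`1` = clusters)
  } else {
    cl <- clusters
    if (is.null(names(cl))) names(cl) <- seq_along(cl)
  }
  bg <- sets$background
  N <- length(bg)
  rows <- list()
  for (cname in names(cl)) {
    query <- intersect(unique(toupper(cl[[cname]])), bg)
    n <- length(query)
    if (n == 0) next
    for (i in seq_len(nrow(sets$terms))) {
      id <- sets$terms$term_id[i]
      mem <- sets$members[[id]]
      k <- length(intersect(query, mem))
      if (k == 0) next
      K <- length(mem)
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cname, collection = sets$terms$collection[i],
        term_id = id, term_name = sets$terms$term_name[i],
        k = k, K = K, n = n, N = N,
        p = hypergeom_upper_tail(k, K, n, N))
    }
  }
  if (length(rows) == 0) {
    return(data.frame(cluster = character(), collection = character(),
                      term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      significant = logical()))
  }
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  for (grp in split(seq_len(nrow(res)),
                    paste(res$cluster, res$collection))) {
    res$q[grp] <- bh_fdr(res$p[grp])
  }
  res$significant <- res$q <= alpha
  res <- res[order(res$cluster, res$q, res$term_id), ]
  rownames(res) <- NULL
  res
}

#' Whole-network PPI enrichment p-value
#'
#' Tests whether the network's proteins are more connected than a random
#' protein set of the same size drawn from a background interactome. Two
#' approximations to this null are provided. `"permutation"`: draw `n_perm`
#' random node sets of the query's size from the background's node
#' universe, count the edges they induce in the background, and report the
#' add-one estimator `p = (1 + #{perm >= observed}) / (n_perm + 1)`, which
#' can never return zero. `"poisson_approx"`: a degree-configuration
#' expectation `lambda = sum over query pairs of min(1, d_i d_j / (2m))`
#' with background degrees `d` and background edge count `m`, and
#' `p = P(Poisson(lambda) >= observed)`.
#'
#' @param net A `ppi_network` (observed edges = its edge count, query = its
#'   node set) or a character vector of query nodes (observed edges counted
#'   in the background).
#' @param background Background edge list: data.frame with `protein_a`,
#'   `protein_b` (extra columns ignored), or a `ppi_network`.
#' @param method `"permutation"` or `"poisson_approx"`.
#' @param n_perm Permutations for the permutation null.
#' @param seed Mandatory RNG seed in permutation mode.
#' @return A list: `p`, `observed_edges`, `expected_edges`, `method`,
#'   `n_query`.
#' @export
ppi_enrichment_pvalue <- function(net, background,
                                  method = c("permutation", "poisson_approx"),
                                  n_perm = 10000L, seed = NULL) {
  method <- match.arg(method)
  if (inherits(background, "ppi_network")) background <- background$edges
  bg <- data.frame(a = toupper(as.character(background$protein_a)),
                   b = toupper(as.character(background$protein_b)))
  bg <- bg[bg$a != bg$b, ]
  universe <- sort(unique(c(bg$a, bg$b)))
  nU <- length(universe)
  A <- matrix(FALSE, nU, nU, dimnames = list(universe, universe))
  ia <- match(bg$a, universe)
  ib <- match(bg$b, universe)
  A[cbind(ia, ib)] <- TRUE
  A[cbind(ib, ia)] <- TRUE
  m_bg <- sum(A) / 2
  deg <- rowSums(A)

  if (inherits(net, "ppi_network")) {
    query <- net$nodes
    observed <- nrow(net$edges)
  } else {
    query <- unique(toupper(as.character(net)))
    qi <- match(query, universe)
    if (anyNA(qi)) {
      stop("query nodes absent from background: ",
           paste(query[is.na(qi)], collapse = ", "))
    }
    observed <- sum(A[qi, qi]) / 2
  }
  qi <- match(query, universe)
  if (anyNA(qi)) {
    stop("query nodes absent from background: ",
         paste(query[is.na(qi)], collapse = ", "))
  }
  q <- length(qi)

  if (method == "permutation") {
    if (is.null(seed)) stop("permutation mode requires a seed")
    set.seed(seed)
    counts <- vapply(seq_len(n_perm), function(r) {
      idx <- sample.int(nU, q)
      sum(A[idx, idx]) / 2
    }, numeric(1))
    p <- (1 + sum(counts >= observed)) / (n_perm + 1)
    expected <- mean(counts)
  } else {
    d <- deg[qi]
    pr <- outer(d, d) / (2 * m_bg)
    pr <- pmin(1, pr[upper.tri(pr)])
    lambda <- sum(pr)
    p <- if (observed <= 0) 1 else stats::ppois(observed - 1, lambda,
                                                lower.tail = FALSE)
    expected <- lambda
  }
  list(p = p, observed_edges = observed, expected_edges = expected,
       method = method, n_query = q)
}
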