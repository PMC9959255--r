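# Network topology: graph assembly, betweenness centrality, topological
# attack, understudied-node ranking, and local over-representation analysis
# against user-supplied gene-set collections.
#
# Graphs are igraph objects with a `type` vertex attribute (gene / TF /
# miRNA / protein); centrality itself is delegated to igraph's exact
# Brandes implementation, and the test suite checks it against an
# exhaustive shortest-path enumeration oracle.

#' Build an annotated graph from an edge table
#'
#' Self-loops are dropped with a warning and parallel edges collapsed, so
#' the result is a simple graph.
#'
#' @param edges Data frame with columns `source`, `target` and optionally
#'   `interaction`, `source_type`, `target_type`.
#' @param directed Treat edges as directed (default `FALSE`; mixed
#'   regulatory figures are analyzed undirected).
#' @return An igraph graph with vertex attribute `type` (default
#'   `"gene"`).
#' @export
build_graph <- function(edges, directed = FALSE) {
  edges <- as.data.frame(edges)
  if (is.null(edges$source) || is.null(edges$target)) {
    stopf("edge table needs `source` and `target` columns")
  }
  loops <- edges$source == edges$target
  if (any(loops)) {
    warnf("dropping %d self-loop(s)", sum(loops))
    edges <- edges[!loops, , drop = FALSE]
  }
  n_e <- nrow(edges)
  src_t <- rep_len(as.character(edges$source_type %||% "gene"), n_e)
  tgt_t <- rep_len(as.character(edges$target_type %||% "gene"), n_e)
  types <- c(stats::setNames(src_t, edges$source),
             stats::setNames(tgt_t, edges$target))
  types <- types[!duplicated(names(types))]
  g <- igraph::graph_from_data_frame(edges[, c("source", "target"), drop = FALSE],
                                     directed = directed)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  igraph::V(g)$type <- unname(types[igraph::V(g)$name])
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Betweenness centrality table
#'
#' Exact shortest-path betweenness; the normalized variant divides by
#' `(n-1)(n-2)/2` for undirected graphs and `(n-1)(n-2)` for directed ones.
#'
#' @param graph An igraph graph.
#' @return Data frame `node`, `betweenness`, `normalized`, sorted by
#'   decreasing betweenness (ties by node id).
#' @export
betweenness_table <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) stopf("empty graph")
  b <- igraph::betweenness(graph, directed = igraph::is_directed(graph),
                           weights = NA)
  denom <- if (igraph::is_directed(graph)) (n - 1) * (n - 2)
           else (n - 1) * (n - 2) / 2
  norm <- if (n > 2) b / denom else rep(0, n)
  out <- data.frame(node = igraph::V(graph)$name, betweenness = unname(b),
                    normalized = unname(norm), stringsAsFactors = FALSE)
  out[order(-out$betweenness, out$node), , drop = FALSE]
}

#' Topological attack curve
#'
#' Iteratively removes the top-ranked node (by betweenness, degree, or a
#' user-given order), recording the largest-connected-component size and
#' component count after each removal.  Ties are broken lexicographically
#' by node id.  With `recompute = TRUE` the ranking is recalculated after
#' every removal; otherwise the initial ranking is used throughout.
#'
#' @param graph An igraph graph.
#' @param strategy `"betweenness"`, `"degree"`, or `"given-order"`.
#' @param recompute Recalculate centrality after each removal.
#' @param order Node ids for `strategy = "given-order"`.
#' @param stop_fraction Stop after removing this fraction of nodes
#'   (default 1: remove everything).
#' @return Data frame: `step`, `removed`, `lcc_size`, `n_components`
#'   (row 0 describes the intact graph).
#' @export
topological_attack <- function(graph, strategy = c("betweenness", "degree", "given-order"),
                               recompute = TRUE, order = NULL, stop_fraction = 1) {
  strategy <- match.arg(strategy)
  n0 <- igraph::vcount(graph)
  if (n0 == 0) stopf("empty graph")
  if (strategy == "given-order" && is.null(order)) stopf("`order` required")

  rank_next <- function(g) {
    score <- switch(strategy,
      betweenness = igraph::betweenness(g, directed = igraph::is_directed(g),
                                        weights = NA),
      degree = igraph::degree(g),
      `given-order` = NULL)
    nm <- igraph::V(g)$name
    nm[order(-score, nm)][1L]
  }

  comp_stats <- function(g) {
    if (igraph::vcount(g) == 0) return(c(0L, 0L))
    cm <- igraph::components(g, mode = "weak")
    c(max(cm$csize), cm$no)
  }

  g <- graph
  init <- comp_stats(g)
  steps <- list(data.frame(step = 0L, removed = NA_character_,
                           lcc_size = init[1], n_components = init[2],
                           stringsAsFactors = FALSE))
  static_order <- if (strategy == "given-order") {
    as.character(order)
  } else if (!recompute) {
    score <- switch(strategy,
      betweenness = igraph::betweenness(graph, directed = igraph::is_directed(graph),
                                        weights = NA),
      degree = igraph::degree(graph))
    nm <- igraph::V(graph)$name
    nm[order(-score, nm)]
  } else NULL

  n_remove <- ceiling(stop_fraction * n0)
  for (k in seq_len(n_remove)) {
    victim <- if (!is.null(static_order)) static_order[k] else rank_next(g)
    if (is.na(victim) || !(victim %in% igraph::V(g)$name)) break
    g <- igraph::delete_vertices(g, victim)
    st <- comp_stats(g)
    steps[[k + 1L]] <- data.frame(step = k, removed = victim,
                                  lcc_size = st[1], n_components = st[2],
                                  stringsAsFactors = FALSE)
  }
  do.call(rbind, steps)
}

#' Rank high-centrality, low-literature-coverage nodes
#'
#' The understudied score is the difference between a node's centrality
#' rank percentile and its literature-count rank percentile; high scores
#' mark highly connected but sparsely studied nodes.
#'
#' @param centrality A [betweenness_table()].
#' @param literature_counts Data frame `node`, `count`; nodes missing from
#'   it get count 0 and `missing_count = TRUE`.
#' @return Data frame sorted by decreasing score: `node`, `betweenness`,
#'   `normalized`, `count`, `centrality_pct`, `literature_pct`, `score`,
#'   `missing_count`.
#' @export
rank_understudied <- function(centrality, literature_counts) {
  lit <- as.data.frame(literature_counts)
  if (is.null(lit$node) || is.null(lit$count)) {
    stopf("`literature_counts` needs `node` and `count` columns")
  }
  out <- centrality
  m <- match(out$node, lit$node)
  out$count <- ifelse(is.na(m), 0, lit$count[m])
  out$missing_count <- is.na(m)
  n <- nrow(out)
  out$centrality_pct <- rank(out$betweenness, ties.method = "average") / n
  out$literature_pct <- rank(out$count, ties.method = "average") / n
  out$score <- out$centrality_pct - out$literature_pct
  out[order(-out$score, out$node), , drop = FALSE]
}

#' Hypergeometric over-representation analysis
#'
#' Tests each collection set for enrichment in the query via the upper-tail
#' hypergeometric probability `P(X >= overlap)` (population = universe,
#' successes = set members in the universe, draws = query size), with
#' Benjamini-Hochberg adjustment across the collection.  Stands in for
#' web-based enrichment services, which are out of scope; supply curated
#' collections as GMT files via [read_gmt()].
#'
#' @param query Character vector of gene ids (must lie in `universe`).
#' @param collections Named list of character vectors (a gene-set library).
#' @param universe Character vector: the gene universe.
#' @return Data frame: `set`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p_hyper`, `p_adj`, sorted by increasing `p_hyper`.
#' @export
ora_enrichment <- function(query, collections, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0) stopf("empty universe")
  if (length(query) == 0) stopf("empty query")
  if (!all(query %in% universe)) {
    stopf("query genes outside the universe: %s",
          paste(utils::head(setdiff(query, universe), 5L), collapse = ", "))
  }
  N <- length(universe)
  nq <- length(query)
  rows <- lapply(names(collections), function(nm) {
    set <- intersect(unique(collections[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(set, query))
    p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, nq, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, query_size = nq,
               universe_size = N, p_hyper = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_hyper)
  out[order(out$p_hyper, out$set), , drop = FALSE]
}
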