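#' Node strength
#'
#' Absolute sum of a node's edge weights, `sum_j |w_ij|`.
#'
#' @param network a [symptom_network()].
#' @param node optional node label; if omitted, all nodes.
#' @return named numeric vector (or scalar for a single node).
#' @export
node_strength <- function(network, node = NULL) {
  stopifnot(inherits(network, "symptom_network"))
  s <- rowSums(abs(network$weights))
  pick_node(s, network, node)
}

#' Expected influence
#'
#' Signed sum of a node's edge weights, `sum_j w_ij` (one-step). Unlike
#' strength, negative edges reduce a node's expected influence, which makes
#' it the better-suited centrality when networks contain negative edges.
#'
#' @inheritParams node_strength
#' @return named numeric vector (or scalar for a single node).
#' @export
expected_influence <- function(network, node = NULL) {
  stopifnot(inherits(network, "symptom_network"))
  pick_node(rowSums(network$weights), network, node)
}

pick_node <- function(v, network, node) {
  names(v) <- network$labels
  if (is.null(node)) return(v)
  if (!node %in% network$labels)
    stop_validation("unknown node label '%s'", node)
  unname(v[node])
}

# all-pairs shortest-path distances on edge lengths 1/|w|
distance_matrix <- function(network) {
  g <- igraph_from_network(network)
  w <- abs(edge_weights_of(g))
  igraph::distances(g, weights = if (length(w)) 1 / w else NULL)
}

#' Closeness centrality
#'
#' Edges are given lengths `1/|w_ij|` (zero edges are non-edges); closeness
#' of a node is `(p - 1) / sum_j d(i, j)` over shortest-path distances. Nodes
#' that cannot reach every other node get closeness 0.
#'
#' @inheritParams node_strength
#' @return named numeric vector (or scalar for a single node).
#' @export
closeness_centrality <- function(network, node = NULL) {
  stopifnot(inherits(network, "symptom_network"))
  D <- distance_matrix(network)
  p <- n_nodes(network)
  tot <- rowSums(D)
  cl <- if (p == 1) 0 else ifelse(is.finite(tot), (p - 1) / tot, 0)
  pick_node(cl, network, node)
}

#' Betweenness centrality
#'
#' Freeman betweenness on the `1/|w|` distance graph: the number of shortest
#' paths between pairs of other nodes that pass through the node, with
#' fractional credit shared among tied shortest paths.
#'
#' @inheritParams node_strength
#' @return named numeric vector (or scalar for a single node).
#' @export
betweenness_centrality <- function(network, node = NULL) {
  stopifnot(inherits(network, "symptom_network"))
  g <- igraph_from_network(network)
  w <- abs(edge_weights_of(g))
  b <- igraph::betweenness(g, directed = FALSE,
                           weights = if (length(w)) 1 / w else NULL)
  pick_node(as.numeric(b), network, node)
}

#' Centrality table
#'
#' Computes the four node-centrality indices (strength, expected influence,
#' closeness, betweenness) for every node, optionally z-standardized.
#'
#' @param network a [symptom_network()].
#' @param standardize return z-scores instead of raw values (see
#'   [standardize_centrality()]).
#' @return data frame with columns `node`, `strength`, `expected_influence`,
#'   `closeness`, `betweenness`.
#' @export
centrality_table <- function(network, standardize = FALSE) {
  tab <- data.frame(node = network$labels,
                    strength = node_strength(network),
                    expected_influence = expected_influence(network),
                    closeness = closeness_centrality(network),
                    betweenness = betweenness_centrality(network),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (standardize) standardize_centrality(tab) else tab
}

#' Standardize a centrality table
#'
#' Converts each centrality index to z-scores, `(x - mean(x)) / sd(x)`, using
#' the sample standard deviation (n-1 denominator). Indices that are constant
#' across nodes get z = 0 everywhere.
#'
#' @param table a centrality table from [centrality_table()].
#' @return the table with each index column z-standardized.
#' @export
standardize_centrality <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) >= 2)
  idx <- setdiff(names(table), "node")
  for (cn in idx) {
    x <- table[[cn]]
    s <- sd(x)
    table[[cn]] <- if (is.na(s) || s == 0) rep(0, length(x)) else
      (x - mean(x)) / s
  }
  table
}
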