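# Hub Explorer / Path Explorer computations: degree and (unnormalized,
# fractionally counted) betweenness centrality per node, top-n ranking, and
# enumeration of all shortest paths between node pairs.

#' Node topology table
#'
#' Per-node degree (number of incident edges) and betweenness centrality
#' (sum over node pairs of the fraction of shortest paths passing through
#' the node; endpoints excluded, each unordered pair counted once,
#' unnormalized). The `expression` column carries the seed logFC or
#' significance count and is `NA` for non-seed nodes (rendered as a dash in
#' the written table).
#'
#' @param net A `ppi_network`.
#' @return A data frame with columns `node`, `degree`, `betweenness`,
#'   `expression`, in node order.
#' @export
topology_table <- function(net) {
  g <- net$graph
  v <- igraph::V(g)
  data.frame(node = v$name,
             degree = unname(igraph::degree(g)),
             betweenness = unname(igraph::betweenness(g, directed = FALSE,
                                                      weights = NA)),
             expression = ifelse(v$is_seed, v$expression, NA_real_),
             stringsAsFactors = FALSE)
}

#' @rdname topology_table
#' @export
degree_table <- function(net) {
  tab <- topology_table(net)
  tab[order(-tab$degree, tab$node), , drop = FALSE]
}

#' @rdname topology_table
#' @export
betweenness_table <- function(net) {
  tab <- topology_table(net)
  tab[order(-tab$betweenness, tab$node), , drop = FALSE]
}

#' Top hub nodes
#'
#' Stable descending sort on the chosen topology measure, ties broken by
#' node ID ascending; the first `n` node IDs are returned (all nodes when
#' `n` exceeds the table).
#'
#' @param table A topology table (see [topology_table()]).
#' @param by `"degree"` or `"betweenness"`.
#' @param n Number of hubs to return.
#' @return Character vector of node IDs.
#' @export
top_nodes <- function(table, by = c("degree", "betweenness"), n = 10L) {
  by <- match.arg(by)
  stopifnot(n >= 1L)
  ord <- order(-table[[by]], table$node)
  head(table$node[ord], n)
}

#' All shortest paths between two nodes
#'
#' Path Explorer: enumerates every distinct shortest path between two nodes
#' of the current network, as node ID sequences in lexicographic order,
#' truncated at `cap`.
#'
#' @param net A `ppi_network`.
#' @param from,to Node IDs.
#' @param cap Maximum number of paths returned.
#' @return List of character vectors (empty when the nodes are
#'   disconnected).
#' @export
list_shortest_paths <- function(net, from, to, cap = 100L) {
  stopifnot(cap >= 1L)
  nodes <- network_nodes(net)
  for (x in c(from, to)) {
    if (!x %in% nodes) stop(sprintf("node '%s' not in network", x), call. = FALSE)
  }
  res <- igraph::all_shortest_paths(net$graph, from = from, to = to,
                                    weights = NA)
  paths <- lapply(res$vpaths, names)
  if (length(paths) == 0L) return(list())
  paths <- paths[order(vapply(paths, paste, "", collapse = "\r"))]
  head(paths, cap)
}
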