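# Subnetwork construction: map seeds onto the interactome and assemble
# induced subgraphs at zero, first or higher interaction order; trim to
# seed-connecting nodes; exclude promiscuous proteins; decompose into the
# "continent" and "island" connected components.

db_graph <- function(db) {
  igraph::graph_from_data_frame(db$interactions, directed = FALSE,
                                vertices = data.frame(name = db$proteins))
}

new_network <- function(graph, order) {
  structure(list(graph = graph, order = order), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network (order %s): %d nodes, %d edges, %d seeds\n",
              as.character(x$order), igraph::vcount(x$graph),
              igraph::ecount(x$graph),
              sum(igraph::V(x$graph)$is_seed)))
  invisible(x)
}

# Seed values keyed by canonical ID; first value wins when several external
# IDs collapse onto one protein.
map_seed_values <- function(db, seeds) {
  ids <- names(seeds$values)
  canon <- unname(db$id_map[ids])
  keep <- !is.na(canon) & canon %in% db$proteins
  canon <- canon[keep]
  vals <- unname(seeds$values)[keep]
  dup <- duplicated(canon)
  if (any(dup)) message(sum(dup), " seed(s) collapsed onto already-seeded proteins")
  setNames(vals[!dup], canon[!dup])
}

#' Node count for a network
#' @param net A `ppi_network`.
#' @return Integer node count.
#' @export
network_size <- function(net) as.integer(igraph::vcount(net$graph))

#' Nodes of a network
#' @param net A `ppi_network`.
#' @return Character vector of node IDs.
#' @export
network_nodes <- function(net) igraph::V(net$graph)$name

#' Edges of a network
#' @param net A `ppi_network`.
#' @return Two-column data frame of unordered node pairs.
#' @export
network_edges <- function(net) {
  e <- igraph::as_edgelist(net$graph)
  data.frame(from = pmin(e[, 1L], e[, 2L]), to = pmax(e[, 1L], e[, 2L]),
             stringsAsFactors = FALSE)
}

induce <- function(db, seed_values, nodes, order) {
  g <- igraph::induced_subgraph(db_graph(db), nodes)
  igraph::V(g)$is_seed <- igraph::V(g)$name %in% names(seed_values)
  igraph::V(g)$expression <- unname(seed_values[igraph::V(g)$name])
  new_network(g, order)
}

#' Build a seed PPI subnetwork
#'
#' Maps the seed set into the interactome and assembles the induced subgraph
#' on either the seeds alone (`order = "zero"`, for very large seed lists) or
#' the seeds plus all of their direct interactors (`order = "first"`, the
#' default network). All interactome edges among member nodes are included;
#' mapped seeds with no interactions are retained as singleton nodes.
#'
#' @param db An `interaction_db`.
#' @param seeds A `seed_set`.
#' @param order `"first"` or `"zero"`.
#' @return A `ppi_network`: igraph graph with per-node `is_seed` and
#'   `expression` attributes plus a construction-order tag (0 or 1).
#' @export
build_network <- function(db, seeds, order = c("first", "zero")) {
  order <- match.arg(order)
  sv <- map_seed_values(db, seeds)
  if (length(sv) == 0L) stop("no seeds in interactome", call. = FALSE)
  g <- db_graph(db)
  nodes <- names(sv)
  if (order == "first") {
    nbr <- igraph::adjacent_vertices(g, nodes)
    nodes <- unique(c(nodes, unlist(lapply(nbr, names), use.names = FALSE)))
  }
  net <- induce(db, sv, nodes, order = if (order == "zero") 0L else 1L)
  check_network_size(net)
  net
}

#' Expand a network to the next interaction order
#'
#' Treats every current node as a new seed and rebuilds the first-order
#' network around them; the original seed flags are preserved and the
#' construction-order tag is incremented.
#'
#' @param db The `interaction_db` the network was built from.
#' @param net A `ppi_network`.
#' @return A `ppi_network` of the next order.
#' @export
expand_order <- function(db, net) {
  g <- db_graph(db)
  nodes <- network_nodes(net)
  nbr <- igraph::adjacent_vertices(g, nodes)
  all_nodes <- unique(c(nodes, unlist(lapply(nbr, names), use.names = FALSE)))
  sv <- seed_values_of(net)
  out <- induce(db, sv, all_nodes, order = net$order + 1L)
  check_network_size(out)
  out
}

seed_values_of <- function(net) {
  v <- igraph::V(net$graph)
  setNames(v$expression[v$is_seed], v$name[v$is_seed])
}

#' Trim a network to nodes connecting the seeds
#'
#' Keeps every seed node plus every non-seed node lying on at least one
#' shortest path (within the current network, unit edge lengths) between
#' some pair of seeds; the edge set is re-induced. Any two seeds connected
#' before trimming remain connected afterwards.
#'
#' @param net A `ppi_network` containing at least two seed nodes.
#' @return The trimmed `ppi_network`.
#' @export
trim_to_minimum <- function(net) {
  g <- net$graph
  seeds <- igraph::V(g)$name[igraph::V(g)$is_seed]
  if (length(seeds) < 2L) stop("trimming needs at least 2 seed nodes", call. = FALSE)
  d <- igraph::distances(g, v = seeds)       # seeds x all nodes
  keep <- logical(igraph::vcount(g))
  names(keep) <- igraph::V(g)$name
  keep[seeds] <- TRUE
  for (i in seq_len(length(seeds) - 1L)) {
    for (j in (i + 1L):length(seeds)) {
      dst <- d[i, seeds[j]]
      if (is.finite(dst)) {
        on_path <- d[i, ] + d[j, ] == dst
        keep[on_path] <- TRUE
      }
    }
  }
  sub <- igraph::induced_subgraph(g, names(keep)[keep])
  new_network(sub, net$order)
}

#' Exclude nodes from a network
#'
#' Removes the listed nodes (e.g. promiscuous proteins known for
#' non-specific interactions) and their incident edges. Absent IDs are
#' ignored with a warning.
#'
#' @param net A `ppi_network`.
#' @param ids Character vector of node IDs to remove.
#' @return The reduced `ppi_network`.
#' @export
exclude_nodes <- function(net, ids) {
  ids <- trimws(as.character(ids))
  present <- ids[ids %in% network_nodes(net)]
  if (length(present) < length(ids)) {
    warning(length(ids) - length(present), " ID(s) not in the network; ignored",
            call. = FALSE)
  }
  new_network(igraph::delete_vertices(net$graph, present), net$order)
}

#' Connected components, continent first
#'
#' Splits the network into connected components sorted by node count
#' descending (ties broken by the lexicographically smallest member). The
#' first component is the "continent"; the rest are "islands".
#'
#' @param net A `ppi_network`.
#' @return A list of `ppi_network`s (empty for an empty network).
#' @export
net_components <- function(net) {
  g <- net$graph
  if (igraph::vcount(g) == 0L) return(list())
  comp <- igraph::components(g)
  members <- split(igraph::V(g)$name, comp$membership)
  first <- vapply(members, function(m) min(m), "")
  ord <- order(-lengths(members), first)
  lapply(members[ord], function(m)
    new_network(igraph::induced_subgraph(g, m), net$order))
}

#' Per-component summary table
#'
#' The Network-Explorer style overview: node, edge and seed counts per
#' connected component, continent first.
#'
#' @param net A `ppi_network`.
#' @return A data frame with columns `component`, `nodes`, `edges`, `seeds`.
#' @export
component_summary <- function(net) {
  comps <- net_components(net)
  data.frame(
    component = seq_along(comps),
    nodes = vapply(comps, network_size, 1L),
    edges = vapply(comps, function(x) as.integer(igraph::ecount(x$graph)), 1L),
    seeds = vapply(comps, function(x) sum(igraph::V(x$graph)$is_seed), 1L))
}

# Size guidance (recommended 200-2000 nodes; advised hard ceiling 5000) is
# advisory only: messages, never errors.
check_network_size <- function(net) {
  n <- network_size(net)
  if (n > 5000L) {
    message("network has ", n, " nodes; above the advised 5000-node limit -- ",
            "consider zero-order construction or stricter seed cutoffs")
  } else if (n > 2000L) {
    message("network has ", n, " nodes; above the recommended 200-2000 range")
  }
  invisible(net)
}
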