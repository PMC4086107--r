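# GraphML interchange: one undirected <graph> with declared attribute keys
# (is_seed boolean, expression double when present, module int when a
# partition is supplied, degree/betweenness when requested), written and read
# with xml2 so export -> import reproduces the network exactly.

GRAPHML_NS <- "http://graphml.graphdrawing.org/xmlns"

#' Export a network as GraphML
#'
#' @param net A non-empty `ppi_network`.
#' @param path Output path.
#' @param partition Optional `module_partition`; adds an integer `module`
#'   node attribute.
#' @param topology Also write `degree` and `betweenness` node attributes.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path, partition = NULL, topology = FALSE) {
  if (network_size(net) == 0L) stop("cannot export an empty network", call. = FALSE)
  g <- net$graph
  v <- igraph::V(g)
  keys <- list(
    c("d_seed", "is_seed", "boolean"),
    c("d_expr", "expression", "double"))
  mem <- NULL
  if (!is.null(partition)) {
    mem <- module_membership(partition)
    keys <- c(keys, list(c("d_mod", "module", "int")))
  }
  topo <- NULL
  if (topology) {
    topo <- topology_table(net)
    rownames(topo) <- topo$node
    keys <- c(keys, list(c("d_deg", "degree", "int"),
                         c("d_btw", "betweenness", "double")))
  }

  doc <- xml2::xml_new_root("graphml", xmlns = GRAPHML_NS)
  for (k in keys) {
    xml2::xml_add_child(doc, "key", id = k[1L], "for" = "node",
                        attr.name = k[2L], attr.type = k[3L])
  }
  xml2::xml_add_child(doc, "key", id = "g_order", "for" = "graph",
                      attr.name = "order", attr.type = "int")
  graph <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  ord <- xml2::xml_add_child(graph, "data", key = "g_order")
  xml2::xml_set_text(ord, as.character(as.integer(net$order)))

  add_data <- function(node, key, text) {
    d <- xml2::xml_add_child(node, "data", key = key)
    xml2::xml_set_text(d, text)
  }
  for (i in seq_along(v)) {
    nd <- xml2::xml_add_child(graph, "node", id = v$name[i])
    add_data(nd, "d_seed", if (isTRUE(v$is_seed[i])) "true" else "false")
    if (!is.na(v$expression[i])) {
      add_data(nd, "d_expr", sprintf("%.15g", v$expression[i]))
    }
    if (!is.null(mem)) add_data(nd, "d_mod", as.character(mem[[v$name[i]]]))
    if (!is.null(topo)) {
      add_data(nd, "d_deg", as.character(topo[v$name[i], "degree"]))
      add_data(nd, "d_btw", sprintf("%.15g", topo[v$name[i], "betweenness"]))
    }
  }
  e <- igraph::as_edgelist(g)
  for (i in seq_len(nrow(e))) {
    xml2::xml_add_child(graph, "edge", source = e[i, 1L], target = e[i, 2L])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a GraphML network
#'
#' Reads GraphML written by [export_graphml()] (or any single undirected
#' graph with compatible node attributes) back into a `ppi_network`.
#'
#' @param path Path to the GraphML file.
#' @return A `ppi_network`; the `module` attribute, when present, is kept as
#'   a vertex attribute.
#' @export
import_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, "./key")
  key_name <- setNames(xml2::xml_attr(keys, "attr.name"),
                       xml2::xml_attr(keys, "id"))
  key_type <- setNames(xml2::xml_attr(keys, "attr.type"),
                       xml2::xml_attr(keys, "id"))
  graph <- xml2::xml_find_first(doc, "./graph")
  if (is.na(xml2::xml_name(graph))) stop("no <graph> element in '", path, "'", call. = FALSE)

  coerce <- function(text, type) {
    switch(type,
           boolean = identical(text, "true"),
           int = as.integer(text),
           long = as.integer(text),
           double = as.numeric(text),
           float = as.numeric(text),
           text)
  }
  nodes <- xml2::xml_find_all(graph, "./node")
  ids <- xml2::xml_attr(nodes, "id")
  attrs <- list(is_seed = rep(FALSE, length(ids)),
                expression = rep(NA_real_, length(ids)),
                module = rep(NA_integer_, length(ids)),
                degree = rep(NA_integer_, length(ids)),
                betweenness = rep(NA_real_, length(ids)))
  for (i in seq_along(nodes)) {
    for (d in xml2::xml_find_all(nodes[[i]], "./data")) {
      k <- xml2::xml_attr(d, "key")
      nm <- key_name[[k]]
      if (nm %in% names(attrs)) {
        attrs[[nm]][i] <- coerce(xml2::xml_text(d), key_type[[k]])
      }
    }
  }
  edges <- xml2::xml_find_all(graph, "./edge")
  e <- data.frame(from = xml2::xml_attr(edges, "source"),
                  to = xml2::xml_attr(edges, "target"),
                  stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = data.frame(name = ids))
  igraph::V(g)$is_seed <- attrs$is_seed[match(igraph::V(g)$name, ids)]
  igraph::V(g)$expression <- attrs$expression[match(igraph::V(g)$name, ids)]
  if (any(!is.na(attrs$module))) {
    igraph::V(g)$module <- attrs$module[match(igraph::V(g)$name, ids)]
  }
  order_node <- xml2::xml_find_first(graph, "./data")
  order <- if (!is.na(xml2::xml_name(order_node))) {
    as.integer(xml2::xml_text(order_node))
  } else NA_integer_
  new_network(g, order)
}
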