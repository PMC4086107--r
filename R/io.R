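# Tab-delimited result writers and the edge-list + node-attribute-sidecar
# network interchange format.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network as an edge list plus node-attribute sidecar
#'
#' Two files: `<prefix>_edges.tsv` (from, to) and `<prefix>_nodes.tsv`
#' (node, is_seed, expression); together they round-trip through
#' [read_network()].
#'
#' @param net A `ppi_network`.
#' @param prefix Path prefix for the two files.
#' @return Character vector of the two paths, invisibly.
#' @export
write_network <- function(net, prefix) {
  edge_path <- paste0(prefix, "_edges.tsv")
  node_path <- paste0(prefix, "_nodes.tsv")
  write_tsv(network_edges(net), edge_path)
  v <- igraph::V(net$graph)
  write_tsv(data.frame(node = v$name, is_seed = v$is_seed,
                       expression = ifelse(is.na(v$expression), "-",
                                           sprintf("%.15g", v$expression)),
                       stringsAsFactors = FALSE),
            node_path)
  invisible(c(edge_path, node_path))
}

#' Read a network from an edge list plus node sidecar
#'
#' @param prefix Path prefix used by [write_network()].
#' @param order Construction-order tag to attach.
#' @return A `ppi_network`.
#' @export
read_network <- function(prefix, order = NA_integer_) {
  edges <- utils::read.table(paste0(prefix, "_edges.tsv"), sep = "\t",
                             header = TRUE, colClasses = "character")
  nodes <- utils::read.table(paste0(prefix, "_nodes.tsv"), sep = "\t",
                             header = TRUE, colClasses = "character")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes$node))
  idx <- match(igraph::V(g)$name, nodes$node)
  igraph::V(g)$is_seed <- nodes$is_seed[idx] == "TRUE"
  expr <- suppressWarnings(as.numeric(nodes$expression[idx]))
  igraph::V(g)$expression <- expr
  new_network(g, order)
}

#' Write a differential-expression table
#' @param de A `de_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) write_tsv(de, path)

#' Write a topology table
#'
#' Non-seed nodes print a dash in the expression column.
#'
#' @param tab A topology table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology_table <- function(tab, path) {
  tab$expression <- ifelse(is.na(tab$expression), "-",
                           sprintf("%.4g", tab$expression))
  write_tsv(tab, path)
}

#' Write a module table
#' @param partition A `module_partition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_module_table <- function(partition, path) {
  s <- partition$stats
  s$p_value <- ifelse(is.na(s$p_value), "-", sprintf("%.6g", s$p_value))
  s$members <- vapply(partition$modules, paste, "", collapse = ";")
  write_tsv(s, path)
}

#' Write an enrichment table
#' @param res An `enrichment_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(res, path) write_tsv(res, path)
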