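#' Graph and table exports
#'
#' Interaction graphs can be written as SIF (for Cytoscape), GraphML (with a
#' `sign` edge attribute) and plain TSV node/edge tables. All outputs are
#' UTF-8 with deterministic row ordering.
#'
#' @name exports
NULL

#' Write an interaction graph as SIF
#'
#' One line per signed edge: `source activates|inhibits target`.
#'
#' @param graph an `interaction_graph`.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_sif <- function(graph, path) {
  stopifnot(inherits(graph, "interaction_graph"))
  e <- graph$edges
  rel <- ifelse(e$sign == "+", "activates", "inhibits")
  lines <- sprintf("%s\t%s\t%s", e$source, rel, e$target)
  isolated <- setdiff(graph$nodes, c(e$source, e$target))
  writeLines(c(lines, isolated), path, useBytes = TRUE)
  invisible(path)
}

#' Write an interaction graph as GraphML
#'
#' @inheritParams write_sif
#' @export
write_graphml <- function(graph, path) {
  g <- ig_to_igraph(graph)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write node/edge TSV tables for an interaction graph
#'
#' @inheritParams write_sif
#' @param nodes_path,edges_path output file paths.
#' @return Invisibly, `c(nodes_path, edges_path)`.
#' @export
write_graph_tables <- function(graph, nodes_path, edges_path) {
  stopifnot(inherits(graph, "interaction_graph"))
  utils::write.table(data.frame(node = graph$nodes), nodes_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(graph$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(nodes_path, edges_path))
}
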