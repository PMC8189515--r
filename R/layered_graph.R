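#' Layered organizational graphs
#'
#' A layered graph is an undirected [igraph::igraph] with two mandatory
#' vertex attributes: `name` (a unique node identifier, stored as character)
#' and `level` (an integer layer index, 1 = staff/base layer, increasing
#' upward through the management hierarchy).  Edges whose endpoints share a
#' level are intra-layer edges; all others are inter-layer edges.  All
#' constructors in this package return graphs of this form and
#' [validate_layered_graph()] enforces the contract.
#'
#' @param graph an igraph object.
#' @return `validate_layered_graph()` returns the graph invisibly, or throws.
#' @examples
#' g <- make_base_rgg(50, k_avg = 6, rng_seed = 1)
#' validate_layered_graph(g)
#' table(node_levels(g))
#' @export
validate_layered_graph <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::is_directed(graph)) stop("layered graph must be undirected")
  lv <- igraph::vertex_attr(graph, "level")
  if (is.null(lv)) stop("missing vertex attribute 'level'")
  lv <- as.integer(lv)
  if (anyNA(lv) || any(lv < 1L)) stop("levels must be integers >= 1")
  nm <- igraph::vertex_attr(graph, "name")
  if (is.null(nm) || anyDuplicated(nm) > 0L) stop("node names must be unique")
  if (igraph::any_loop(graph)) stop("self-loops are not allowed")
  if (igraph::any_multiple(graph)) stop("duplicate edges are not allowed")
  invisible(graph)
}

#' @describeIn validate_layered_graph integer layer index of every node.
#' @export
node_levels <- function(graph) {
  as.integer(igraph::vertex_attr(graph, "level"))
}

#' @describeIn validate_layered_graph logical vector, one entry per edge,
#'   `TRUE` for intra-layer edges (endpoints on the same level).
#' @export
is_intra_edge <- function(graph) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  lv <- node_levels(graph)
  lv[el[, 1L]] == lv[el[, 2L]]
}

#' Number of nodes per layer
#'
#' @param graph a layered graph.
#' @return named integer vector of layer sizes, names are layer indices.
#' @export
layer_sizes <- function(graph) {
  lv <- node_levels(graph)
  tab <- table(factor(lv, levels = sort(unique(lv))))
  stats::setNames(as.integer(tab), names(tab))
}

# internal: build a layered igraph from ids, levels and an edge matrix of ids
new_layered_graph <- function(ids, levels, edges) {
  ids <- as.character(ids)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  g <- igraph::set_vertex_attr(g, "level", value = as.integer(levels))
  if (length(edges) > 0L && nrow(edges) > 0L) {
    g <- igraph::add_edges(g, t(matrix(match(as.character(edges), ids),
                                       nrow = nrow(edges))))
  }
  validate_layered_graph(g)
  g
}
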