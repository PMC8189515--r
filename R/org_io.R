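#' Read an organizational network from CSV node and edge lists
#'
#' The node list must have columns `node_id` and `level` (header names are
#' matched case-insensitively; the first two columns are used as a
#' fallback).  The edge list must have columns `source` and `target` (same
#' fallback).  Edges are undirected and deduplicated order-insensitively;
#' every endpoint must appear in the node list.
#'
#' @param node_csv path to the node-list CSV.
#' @param edge_csv path to the edge-list CSV.
#' @return a layered graph.
#' @seealso [write_org_network()], [threshold_weighted_edges()]
#' @export
read_org_network <- function(node_csv, edge_csv) {
  nodes <- utils::read.csv(node_csv, stringsAsFactors = FALSE)
  edges <- utils::read.csv(edge_csv, stringsAsFactors = FALSE)
  pick <- function(df, wanted, fallback) {
    hit <- match(wanted, tolower(names(df)))
    if (!is.na(hit)) df[[hit]] else df[[fallback]]
  }
  ids <- as.character(pick(nodes, "node_id", 1L))
  lev <- as.integer(pick(nodes, "level", 2L))
  if (anyDuplicated(ids) > 0L) stop("duplicate node ids in node list")
  if (anyNA(lev) || any(lev < 1L)) stop("malformed level column")
  if (nrow(edges) > 0L) {
    u <- as.character(pick(edges, "source", 1L))
    v <- as.character(pick(edges, "target", 2L))
    if (!all(u %in% ids) || !all(v %in% ids)) {
      stop("edge list references node ids absent from the node list")
    }
    if (any(u == v)) stop("self-loops are not allowed")
    key <- ifelse(u < v, paste(u, v), paste(v, u))
    keep <- !duplicated(key)
    em <- cbind(u[keep], v[keep])
  } else {
    em <- matrix(character(0), ncol = 2)
  }
  new_layered_graph(ids, lev, em)
}

#' Write an organizational network to CSV node and edge lists
#'
#' Inverse of [read_org_network()]: writes `node_id, level` and
#' `source, target` CSVs such that reading them back reproduces the graph.
#'
#' @param graph a layered graph.
#' @param node_csv,edge_csv output paths.
#' @return invisibly, the graph.
#' @export
write_org_network <- function(graph, node_csv, edge_csv) {
  validate_layered_graph(graph)
  utils::write.csv(data.frame(node_id = igraph::V(graph)$name,
                              level = node_levels(graph)),
                   node_csv, row.names = FALSE)
  el <- igraph::as_edgelist(graph)
  utils::write.csv(data.frame(source = el[, 1L], target = el[, 2L]),
                   edge_csv, row.names = FALSE)
  invisible(graph)
}

#' Threshold a weighted edge list
#'
#' Keeps edges whose weight is strictly greater than `threshold` — the rule
#' used to turn co-working hours (or message counts) into unweighted
#' collaboration edges.
#'
#' @param records data.frame with columns `source`, `target`, `weight`
#'   (first three columns as fallback).
#' @param threshold non-negative cutoff; edges with `weight > threshold`
#'   survive.
#' @return the surviving rows of `records`.
#' @export
threshold_weighted_edges <- function(records, threshold) {
  stopifnot(threshold >= 0)
  w <- if ("weight" %in% names(records)) records$weight else records[[3L]]
  stopifnot(all(w >= 0))
  records[w > threshold, , drop = FALSE]
}

#' Choose a weight threshold matching a target mean degree
#'
#' Scans the sorted unique weights and returns the cutoff whose surviving
#' edge count is closest to `k_target * n_nodes / 2`, the edge count of a
#' graph with the requested mean degree.
#'
#' @param records weighted edge data.frame as in [threshold_weighted_edges()].
#' @param k_target target mean degree.
#' @param n_nodes number of nodes the degree is averaged over.
#' @return the selected threshold (one of `0` or the unique weights).
#' @export
choose_weight_threshold <- function(records, k_target, n_nodes) {
  w <- if ("weight" %in% names(records)) records$weight else records[[3L]]
  target_edges <- k_target * n_nodes / 2
  cand <- c(0, sort(unique(w)))
  surviving <- vapply(cand, function(th) sum(w > th), 0L)
  cand[which.min(abs(surviving - target_edges))]
}

#' Per-layer network statistics
#'
#' Mean closeness centrality, mean degree and mean local clustering
#' coefficient for each layer and over all nodes.  Closeness is computed on
#' the full multilayer graph (layer subgraphs of a tree-coupled hierarchy
#' are typically disconnected, which would leave closeness ill-defined) and
#' uses the component-size-normalized form
#' `C(u) = ((n_u - 1) / (N - 1)) * ((n_u - 1) / sum of distances)`, where
#' `n_u` counts the nodes reachable from `u`; for a connected graph this is
#' ordinary normalized closeness.  Local clustering of degree < 2 nodes is
#' 0.
#'
#' @param graph a layered graph.
#' @return data.frame with one row per layer plus a `"Total"` row, columns
#'   `layer`, `n`, `closeness`, `degree`, `clustering`, and an attribute
#'   `connected` flagging whether the graph is connected.
#' @export
layer_stats <- function(graph) {
  validate_layered_graph(graph)
  n <- igraph::vcount(graph)
  stopifnot(n >= 1)
  lv <- node_levels(graph)
  deg <- igraph::degree(graph)
  clust <- igraph::transitivity(graph, type = "localundirected",
                                isolates = "zero")
  clust[deg < 2] <- 0

  dmat <- igraph::distances(graph)
  close <- vapply(seq_len(n), function(u) {
    d <- dmat[u, -u]
    reach <- is.finite(d)
    nr <- sum(reach)
    if (nr == 0L || n == 1L) return(0)
    (nr / (n - 1)) * (nr / sum(d[reach]))
  }, 0)

  levels_present <- sort(unique(lv))
  rows <- lapply(levels_present, function(l) {
    idx <- lv == l
    data.frame(layer = as.character(l), n = sum(idx),
               closeness = mean(close[idx]), degree = mean(deg[idx]),
               clustering = mean(clust[idx]))
  })
  out <- rbind(do.call(rbind, rows),
               data.frame(layer = "Total", n = n, closeness = mean(close),
                          degree = mean(deg), clustering = mean(clust)))
  rownames(out) <- NULL
  attr(out, "connected") <- igraph::is_connected(graph)
  out
}
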