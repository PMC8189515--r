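#' Random geometric staff layer
#'
#' Places `n_staff` nodes uniformly in the unit square and connects every
#' pair at Euclidean distance at most `r = sqrt(k_avg / (n_staff * pi))`,
#' the radius for which a disc of radius `r` holds `k_avg` expected
#' neighbours at the bulk density (edges of the square thin this out
#' slightly, as in any hard-boundary geometric graph).  All nodes are
#' placed on level 1.
#'
#' @param n_staff number of staff nodes (>= 2).
#' @param k_avg target mean degree, > 0.
#' @param rng_seed integer seed; the layout and edge set are a deterministic
#'   function of it.
#' @return a layered graph (see [validate_layered_graph()]) with vertex
#'   attributes `x`, `y` holding the coordinates.
#' @examples
#' g <- make_base_rgg(200, k_avg = 10, rng_seed = 42)
#' mean(igraph::degree(g))
#' @export
make_base_rgg <- function(n_staff, k_avg, rng_seed) {
  stopifnot(n_staff >= 2, k_avg > 0)
  radius <- sqrt(k_avg / (n_staff * pi))
  if (radius >= sqrt(2)) {
    stop("k_avg implies a connection radius >= the diameter of the unit square")
  }
  set.seed(rng_seed)
  coords <- cbind(stats::runif(n_staff), stats::runif(n_staff))
  g <- rgg_from_coords(coords, radius)
  g <- igraph::set_vertex_attr(g, "x", value = coords[, 1L])
  g <- igraph::set_vertex_attr(g, "y", value = coords[, 2L])
  g
}

#' @describeIn make_base_rgg deterministic geometric graph from given
#'   coordinates (rows of `coords`), edge iff distance `<= radius`
#'   (inclusive boundary).
#' @param coords two-column matrix of point coordinates.
#' @param radius connection radius.
#' @export
rgg_from_coords <- function(coords, radius) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  adj <- d <= radius
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  ids <- as.character(seq_len(n))
  new_layered_graph(ids, rep(1L, n),
                    cbind(ids[idx[, 1L]], ids[idx[, 2L]]))
}

#' Fluid-communities partition of the staff layer
#'
#' Partitions the base layer into exactly `c` communities with the fluid
#' communities algorithm (c fluids seeded at random nodes expand and
#' displace each other by local fluid density until stable), which covers
#' the whole layer with a requested number of communities.  The graph must
#' be connected; disconnected draws are rejected (see
#' [build_synthetic_hierarchy()] for the retry policy).
#'
#' @param graph a connected single-layer graph.
#' @param c number of communities, `1 <= c <= vcount(graph)`.
#' @param rng_seed integer seed.
#' @return integer vector of community memberships in `1..c`, one entry per
#'   node, in vertex order.
#' @export
partition_fluid <- function(graph, c, rng_seed) {
  n <- igraph::vcount(graph)
  stopifnot(c >= 1, c <= n)
  if (!igraph::is_connected(graph)) {
    stop("fluid communities require a connected graph")
  }
  set.seed(rng_seed)
  comm <- igraph::cluster_fluid_communities(graph, no.of.communities = c)
  m <- as.integer(igraph::membership(comm))
  if (length(unique(m)) != c) stop("fluid partition did not return c communities")
  m
}

#' Attach a management layer
#'
#' Spawns one manager node per community on the next level up, connects
#' manager j to every node of community j (inter-layer edges), and wires
#' the managers among themselves according to `topology`:
#' \describe{
#'   \item{isolated}{no manager-manager edges}
#'   \item{full}{complete graph on the managers}
#'   \item{er}{Erdos-Renyi G(c, p) with `p = manager_k_or_p`}
#'   \item{rgg}{random geometric graph with radius
#'     `sqrt(manager_k_or_p / (c * pi))`, i.e. targeting mean degree
#'     `manager_k_or_p`}
#'   \item{ba}{Barabasi-Albert preferential attachment with
#'     `round(manager_k_or_p / 2)` edges per new node (mean degree of a BA
#'     graph is about twice the attachment count)}
#' }
#'
#' @param base a layered graph whose top level carries the communities.
#' @param partition integer community memberships for the base-layer nodes
#'   (vertex order), as returned by [partition_fluid()].
#' @param topology one of `"isolated"`, `"full"`, `"er"`, `"rgg"`, `"ba"`.
#' @param manager_k_or_p mean degree (rgg, ba) or connection probability
#'   (er); ignored for isolated and full.
#' @param rng_seed integer seed for the random manager topologies.
#' @return the combined two-layer graph; manager nodes are named
#'   `"m<j>"` and sit one level above the base layer's maximum level.
#' @export
attach_management_layer <- function(base, partition, topology,
                                    manager_k_or_p = NA_real_, rng_seed = 1L) {
  validate_layered_graph(base)
  topology <- match.arg(topology, c("isolated", "full", "er", "rgg", "ba"))
  n <- igraph::vcount(base)
  stopifnot(length(partition) == n)
  cc <- max(partition)
  if (!setequal(unique(partition), seq_len(cc))) {
    stop("partition must use community ids 1..c with no gaps")
  }
  mgr_level <- max(node_levels(base)) + 1L
  mgr_ids <- paste0("m", seq_len(cc))

  g <- igraph::add_vertices(base, cc, name = mgr_ids, level = mgr_level)
  base_names <- igraph::vertex_attr(base, "name")
  # manager j downstream to all of community j
  inter <- rbind(mgr_ids[partition], base_names)
  g <- igraph::add_edges(g, match(as.vector(inter), igraph::V(g)$name))

  mgr_edges <- switch(topology,
    isolated = NULL,
    full = t(utils::combn(cc, 2L)),
    er = {
      if (is.na(manager_k_or_p) || manager_k_or_p < 0 || manager_k_or_p > 1) {
        stop("er topology needs a connection probability in [0, 1]")
      }
      set.seed(rng_seed)
      eg <- igraph::sample_gnp(cc, manager_k_or_p)
      igraph::as_edgelist(eg, names = FALSE)
    },
    rgg = {
      if (is.na(manager_k_or_p) || manager_k_or_p <= 0) {
        stop("rgg topology needs a positive target mean degree")
      }
      set.seed(rng_seed)
      coords <- cbind(stats::runif(cc), stats::runif(cc))
      mg <- rgg_from_coords(coords, sqrt(manager_k_or_p / (cc * pi)))
      igraph::as_edgelist(mg, names = FALSE)
    },
    ba = {
      if (is.na(manager_k_or_p) || manager_k_or_p <= 0) {
        stop("ba topology needs a positive target mean degree")
      }
      set.seed(rng_seed)
      bg <- igraph::sample_pa(cc, m = max(1L, round(manager_k_or_p / 2)),
                              directed = FALSE)
      igraph::as_edgelist(bg, names = FALSE)
    }
  )
  if (!is.null(mgr_edges) && nrow(mgr_edges) > 0L) {
    mgr_vertex <- match(mgr_ids, igraph::V(g)$name)
    g <- igraph::add_edges(g, as.vector(t(cbind(mgr_vertex[mgr_edges[, 1L]],
                                                mgr_vertex[mgr_edges[, 2L]]))))
  }
  validate_layered_graph(g)
  g
}

#' Build the full synthetic two-layer hierarchy
#'
#' Composes [make_base_rgg()], [partition_fluid()] and
#' [attach_management_layer()]: a random geometric staff layer of
#' `n_staff` nodes at target mean degree `k_avg`, partitioned into
#' `c = round(c_frac * n_staff)` fluid communities, each headed by one
#' manager on level 2.  If the staff RGG draw is disconnected (rare at the
#' default density) it is regenerated with the next seed, up to
#' `max_retries` times.
#'
#' @param n_staff staff-layer size.
#' @param k_avg target staff mean degree (default 20).
#' @param c_frac manager fraction of the staff layer (default 0.06).
#' @param manager_topology manager wiring, see [attach_management_layer()].
#' @param manager_k_or_p manager topology parameter.
#' @param rng_seed integer seed; the result is deterministic given it.
#' @param max_retries connectivity retries for the staff RGG.
#' @return list with elements `graph` (the layered graph) and `partition`
#'   (staff community memberships).
#' @examples
#' h <- build_synthetic_hierarchy(300, k_avg = 12, rng_seed = 7)
#' layer_sizes(h$graph)
#' @export
build_synthetic_hierarchy <- function(n_staff, k_avg = 20, c_frac = 0.06,
                                      manager_topology = "isolated",
                                      manager_k_or_p = NA_real_,
                                      rng_seed = 1L, max_retries = 20L) {
  stopifnot(c_frac > 0, c_frac < 1, round(c_frac * n_staff) >= 1)
  cc <- as.integer(round(c_frac * n_staff))
  base <- NULL
  seed <- as.integer(rng_seed)
  for (try in seq_len(max_retries)) {
    cand <- make_base_rgg(n_staff, k_avg, seed)
    if (igraph::is_connected(cand)) {
      base <- cand
      break
    }
    seed <- seed + 1000003L
  }
  if (is.null(base)) {
    stop("could not draw a connected staff RGG within the retry budget")
  }
  part <- partition_fluid(base, cc, rng_seed = seed)
  g <- attach_management_layer(base, part, manager_topology, manager_k_or_p,
                               rng_seed = seed)
  list(graph = g, partition = part)
}
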