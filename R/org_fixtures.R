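#' Line-organization fixture: department cliques under a manager tree
#'
#' Generates a synthetic administrative hierarchy of the kind a formal
#' org chart induces: the base layer is a disjoint union of department
#' cliques, each department has one level-2 manager connected down to all
#' its members; managers are grouped under higher-level managers
#' (round-robin, evenly), each sibling group forms an intra-layer clique
#' and each manager connects up to its group manager; a single apex node
#' tops the tree, so the whole graph is connected.
#'
#' @param dept_counts integer vector of group counts per management level,
#'   bottom-up (e.g. `c(60, 12, 3)`: 60 departments, 12 second-level
#'   groups, 3 third-level groups); an apex node is added on top, so the
#'   graph has `length(dept_counts) + 2` layers.
#' @param dept_size_mean mean department size; sizes are drawn as
#'   `1 + Poisson(dept_size_mean - 1)`.
#' @param rng_seed integer seed.
#' @return a layered graph.
#' @examples
#' g <- make_lineorg_fixture(c(6, 2), dept_size_mean = 5, rng_seed = 1)
#' layer_sizes(g)
#' @export
make_lineorg_fixture <- function(dept_counts, dept_size_mean, rng_seed) {
  stopifnot(length(dept_counts) >= 1, all(dept_counts >= 1),
            all(diff(dept_counts) < 0 | length(dept_counts) == 1),
            dept_size_mean >= 1)
  set.seed(rng_seed)
  n_dept <- dept_counts[1L]
  sizes <- 1L + stats::rpois(n_dept, dept_size_mean - 1)

  ids <- character(0)
  levels <- integer(0)
  edges <- list()
  # staff: one clique per department
  staff_ids <- paste0("s", seq_len(sum(sizes)))
  staff_dept <- rep(seq_len(n_dept), sizes)
  ids <- c(ids, staff_ids)
  levels <- c(levels, rep(1L, length(staff_ids)))
  for (d in seq_len(n_dept)) {
    members <- staff_ids[staff_dept == d]
    if (length(members) >= 2L) {
      edges[[length(edges) + 1L]] <-
        t(utils::combn(members, 2L))
    }
  }

  # management levels; parent assignment round-robin keeps groups even
  child_ids <- staff_ids
  child_group <- staff_dept
  for (l in seq_along(dept_counts)) {
    m <- dept_counts[l]
    mgr_ids <- paste0("m", l, "_", seq_len(m))
    ids <- c(ids, mgr_ids)
    levels <- c(levels, rep(l + 1L, m))
    # manager g of this level heads group g of the children
    edges[[length(edges) + 1L]] <-
      cbind(mgr_ids[child_group], child_ids)
    # sibling cliques: managers sharing a parent on the next level up
    parent_of <- ((seq_len(m) - 1L) %%
                    if (l < length(dept_counts)) dept_counts[l + 1L] else 1L) + 1L
    for (p in unique(parent_of)) {
      sib <- mgr_ids[parent_of == p]
      if (length(sib) >= 2L) {
        edges[[length(edges) + 1L]] <- t(utils::combn(sib, 2L))
      }
    }
    child_ids <- mgr_ids
    child_group <- parent_of
  }

  apex <- "apex"
  ids <- c(ids, apex)
  levels <- c(levels, length(dept_counts) + 2L)
  edges[[length(edges) + 1L]] <- cbind(apex, child_ids)

  new_layered_graph(ids, levels, do.call(rbind, edges))
}

#' Project-style fixture: hub-skewed co-working graph under a manager tree
#'
#' Generates a synthetic collaboration network with the same inter-layer
#' manager tree as [make_lineorg_fixture()] but intra-layer edges drawn
#' from a Chung-Lu model with heavy-tailed (Pareto) expected degrees whose
#' mean increases with layer over the first three layers — emulating a
#' centralized co-working structure in which lower management forms the
#' major hub.
#'
#' @param dept_counts group counts per management level, bottom-up, as in
#'   [make_lineorg_fixture()].
#' @param dept_size_mean mean department size.
#' @param k_avg target overall mean degree.
#' @param hub_skew Pareto shape of the intra-layer expected-degree
#'   distribution (smaller = heavier hubs; default 2.5).
#' @param rng_seed integer seed.
#' @return a layered graph.
#' @export
make_project_fixture <- function(dept_counts, dept_size_mean, k_avg = 20,
                                 hub_skew = 2.5, rng_seed = 1L) {
  stopifnot(k_avg > 0, hub_skew > 1)
  set.seed(rng_seed)
  # reuse the tree skeleton: same nodes and inter-layer edges
  skeleton <- make_lineorg_fixture(dept_counts, dept_size_mean,
                                   rng_seed = rng_seed)
  lv <- node_levels(skeleton)
  nms <- igraph::V(skeleton)$name
  el <- igraph::as_edgelist(skeleton)
  inter <- el[!is_intra_edge(skeleton), , drop = FALSE]

  n <- length(nms)
  n_layers <- max(lv)
  # intra-layer mean-degree profile: rising through layers 1-3, modest above
  profile <- c(1, 6, 7, rep(0.8, max(0, n_layers - 3)))[seq_len(n_layers)]
  layer_n <- tabulate(lv, n_layers)
  inter_deg_total <- 2 * nrow(inter)
  intra_deg_needed <- k_avg * n - inter_deg_total
  if (intra_deg_needed <= 0) {
    stop("k_avg infeasible: the manager tree alone exceeds it")
  }
  # scale the profile so the overall mean degree hits k_avg, honouring the
  # per-layer density cap (a layer cannot exceed mean degree n_l - 1)
  cap <- pmax(layer_n - 1, 0)
  tot <- function(s) sum(pmin(profile * s, cap) * layer_n)
  if (tot(1e6) <= intra_deg_needed) {
    target <- cap  # saturated: as dense as the layers allow
  } else {
    s <- stats::uniroot(function(s) tot(s) - intra_deg_needed,
                        c(0, 1e6), tol = 1e-9)$root
    target <- pmin(profile * s, cap)
  }

  edges <- list(inter)
  for (l in seq_len(n_layers)) {
    idx <- which(lv == l)
    nl <- length(idx)
    if (nl < 2L || target[l] <= 0) next
    # Pareto weights; the edge-probability scale is solved so that the
    # clipped Chung-Lu probabilities sum to the layer's target edge count
    w <- (stats::runif(nl)^(-1 / hub_skew))
    q <- outer(w, w)
    diag(q) <- 0
    target_edges <- target[l] * nl / 2
    f <- function(a) sum(pmin(1, a * q[upper.tri(q)])) - target_edges
    alpha <- if (f(1e8) <= 0) 1e8 else
      stats::uniroot(f, c(1e-12, 1e8), tol = 1e-10)$root
    p <- alpha * q
    p[p > 1] <- 1
    draw <- matrix(stats::runif(nl * nl), nl, nl)
    hit <- which(draw < p & upper.tri(p), arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      edges[[length(edges) + 1L]] <- cbind(nms[idx[hit[, 1L]]],
                                           nms[idx[hit[, 2L]]])
    }
  }
  new_layered_graph(nms, lv, do.call(rbind, edges))
}
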