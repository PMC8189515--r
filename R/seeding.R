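#' Onion decomposition of a graph
#'
#' Iterative peeling refinement of the k-core number: the peeling
#' threshold starts at the minimum degree, every node whose remaining
#' degree is at or below the threshold is removed in one round (one onion
#' layer), and the threshold rises to the new minimum degree only once no
#' remaining node sits at or below it.  A node's onion layer is the round
#' at which it is removed, so layers refine the k-core shells from the
#' periphery (layer 1) towards the deepest core.
#'
#' @param graph an igraph object.
#' @return named integer vector of onion layer indices (1 = first peeled),
#'   one per node, in vertex order.
#' @examples
#' onion_layers(igraph::make_star(6, mode = "undirected"))
#' @export
onion_layers <- function(graph) {
  n <- igraph::vcount(graph)
  stopifnot(n >= 1)
  deg <- igraph::degree(graph)
  adj <- igraph::as_adj_list(graph)
  alive <- rep(TRUE, n)
  layer <- integer(n)
  round <- 0L
  remaining <- n
  threshold <- 0L
  while (remaining > 0L) {
    threshold <- max(threshold, min(deg[alive]))
    round <- round + 1L
    peel <- which(alive & deg <= threshold)
    layer[peel] <- round
    alive[peel] <- FALSE
    remaining <- remaining - length(peel)
    for (v in peel) {
      nb <- as.integer(adj[[v]])
      nb <- nb[alive[nb]]
      deg[nb] <- deg[nb] - 1L
    }
  }
  stats::setNames(layer, igraph::V(graph)$name)
}

#' VoteRank influential-spreader ranking
#'
#' Iterative election of influential spreaders: every node starts with
#' voting ability 1; each round every node's score is the summed voting
#' ability of its neighbours, the highest-scoring unelected node is
#' elected, its own voting ability drops to 0 and each of its neighbours
#' loses `1/<k>` voting ability (floored at 0), where `<k>` is the graph's
#' mean degree.  Election stops early once no remaining node collects a
#' positive score.  Ties are broken by higher degree, then lower vertex
#' index.
#'
#' @param graph an igraph object.
#' @param k number of nodes to elect (default all electable).
#' @return character vector of elected node names in election order.
#' @export
vote_rank <- function(graph, k = igraph::vcount(graph)) {
  n <- igraph::vcount(graph)
  stopifnot(n >= 1)
  adj <- igraph::as_adj_list(graph)
  deg <- igraph::degree(graph)
  avg_deg <- mean(deg)
  ability <- rep(1, n)
  elected <- integer(0)
  is_elected <- rep(FALSE, n)
  for (round in seq_len(min(k, n))) {
    score <- vapply(seq_len(n),
                    function(v) sum(ability[as.integer(adj[[v]])]), 0)
    score[is_elected] <- -Inf
    best <- max(score)
    if (!is.finite(best) || best <= 0) break
    cand <- which(score == best)
    cand <- cand[order(-deg[cand], cand)][1L]
    elected <- c(elected, cand)
    is_elected[cand] <- TRUE
    ability[cand] <- 0
    nb <- as.integer(adj[[cand]])
    if (avg_deg > 0) ability[nb] <- pmax(ability[nb] - 1 / avg_deg, 0)
  }
  igraph::V(graph)$name[elected]
}

#' Select seed nodes
#'
#' Chooses the initially adopted nodes according to a [seed_spec()]:
#' \describe{
#'   \item{random}{uniform sample without replacement from the level}
#'   \item{degree}{highest total degree (all layers pooled) within the level}
#'   \item{voterank}{[vote_rank()] election order computed on the full
#'     multilayer graph, filtered to the level; if the election exhausts
#'     before `count` nodes, the remainder is filled in degree order}
#'   \item{onion}{deepest [onion_layers()] index within the level}
#' }
#' `level = "all"` removes the layer filter.  Deterministic strategies
#' break ties by higher degree, then lower vertex index, so they are
#' reproducible without randomness.
#'
#' @param graph a layered graph.
#' @param spec a [seed_spec()].
#' @param rng_seed integer seed, used only by the `"random"` strategy.
#' @return character vector of `spec$count` seed node names.
#' @examples
#' h <- build_synthetic_hierarchy(200, k_avg = 10, rng_seed = 3)
#' select_seeds(h$graph, seed_spec("degree", level = 2, count = 3))
#' @export
select_seeds <- function(graph, spec, rng_seed = 1L) {
  validate_layered_graph(graph)
  stopifnot(inherits(spec, "seed_spec"))
  lv <- node_levels(graph)
  eligible <- if (identical(spec$level, "all")) {
    seq_along(lv)
  } else {
    which(lv == as.integer(spec$level))
  }
  if (length(eligible) == 0L) stop("no nodes on the requested level")
  if (spec$count > length(eligible)) {
    stop("seed count exceeds the number of eligible nodes")
  }
  if (spec$count == 0L) return(character(0))
  names_all <- igraph::V(graph)$name
  deg <- igraph::degree(graph)

  picked <- switch(spec$strategy,
    random = {
      set.seed(as.integer(rng_seed %% 2147483647))
      eligible[sample.int(length(eligible), spec$count)]
    },
    degree = eligible[order(-deg[eligible], eligible)][seq_len(spec$count)],
    voterank = {
      order_names <- vote_rank(graph)
      ord <- match(order_names, names_all)
      ord <- ord[ord %in% eligible]
      if (length(ord) < spec$count) {
        rest <- setdiff(eligible[order(-deg[eligible], eligible)], ord)
        ord <- c(ord, rest)
      }
      ord[seq_len(spec$count)]
    },
    onion = {
      on <- onion_layers(graph)
      eligible[order(-on[eligible], -deg[eligible],
                     eligible)][seq_len(spec$count)]
    }
  )
  names_all[picked]
}
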