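# Small graphs built in code for the unit tests.

# path graph with names "1".."n", all on level 1
path_graph <- function(n, levels = rep(1L, n)) {
  g <- igraph::make_ring(n, circular = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n)))
  igraph::set_vertex_attr(g, "level", value = as.integer(levels))
}

# two nodes joined by one edge; levels configurable (manager-staff dyad)
dyad_graph <- function(levels = c(1L, 2L)) {
  g <- igraph::make_graph(~ a - b)
  igraph::set_vertex_attr(g, "level", value = as.integer(levels))
}

clique_graph <- function(n, level = 1L) {
  g <- igraph::make_full_graph(n)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n)))
  igraph::set_vertex_attr(g, "level", value = rep(as.integer(level), n))
}

# 10-node test graph with known VoteRank / onion structure
toy10_graph <- function() {
  el <- rbind(c(1, 2), c(1, 3), c(2, 3), c(2, 4), c(3, 4), c(4, 5),
              c(5, 6), c(5, 7), c(6, 7), c(4, 8), c(8, 9), c(9, 10),
              c(8, 10), c(2, 5))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(1:10))
  igraph::set_vertex_attr(g, "level", value = rep(1L, 10))
}

# deterministic-dose parameter set: threshold exactly 1, dose exactly `dose`
deterministic_params <- function(dose = 2, T = 1L, r = 0, si_mode = r == 0,
                                 ...) {
  dosage_params(T = T, r = if (si_mode) 0 else r, threshold_mean = 1,
                threshold_sd = 0, dose_mean = dose, dose_sd = 0,
                si_mode = si_mode, ...)
}

# exact expected consensus time (in micro-steps) for SI dynamics with
# deterministic above-threshold doses on an arbitrary small graph:
# enumerate the Markov chain over infected subsets (a susceptible listener
# adopts iff its chosen speaker is infected).
si_expected_consensus_steps <- function(graph, seed_vertex) {
  n <- igraph::vcount(graph)
  adj <- igraph::as_adj_list(graph)
  subsets <- lapply(0:(2^n - 1), function(b) which(bitwAnd(b, 2^(0:(n - 1))) > 0))
  enc <- function(s) sum(2^(s - 1)) + 1
  full <- enc(seq_len(n))
  # expected steps E[s] satisfy E = 1 + sum_t P(s->t) E[t], E[full] = 0
  reachable <- which(vapply(subsets, function(s) seed_vertex %in% s, TRUE))
  idx <- stats::setNames(seq_along(reachable), reachable)
  m <- length(reachable)
  A <- diag(m)
  b <- rep(1, m)
  for (k in seq_len(m)) {
    s <- subsets[[reachable[k]]]
    if (enc(s) == full) {
      A[k, ] <- 0; A[k, k] <- 1; b[k] <- 0
      next
    }
    stay <- 1
    for (v in setdiff(seq_len(n), s)) {
      nb <- as.integer(adj[[v]])
      p_flip <- (1 / n) * sum(nb %in% s) / length(nb)
      if (p_flip > 0) {
        t_enc <- enc(sort(c(s, v)))
        A[k, idx[[as.character(t_enc)]]] <-
          A[k, idx[[as.character(t_enc)]]] - p_flip
        stay <- stay - p_flip
      }
    }
    A[k, k] <- A[k, k] - stay
  }
  solve(A, b)[idx[[as.character(enc(seed_vertex))]]]
}
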