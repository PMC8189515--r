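#' Seed count for a community-sized seed
#'
#' The standard "established community" seed is 1.5% of the whole system,
#' `round(0.015 * N_total)`, as opposed to the minimal single-node seed.
#'
#' @param graph a layered graph.
#' @param frac seed fraction (default 0.015).
#' @return integer seed count, at least 1.
#' @export
community_seed_count <- function(graph, frac = 0.015) {
  max(1L, as.integer(round(frac * igraph::vcount(graph))))
}

#' Peak-adoption table across manager wiring strategies
#'
#' For each combination of manager topology, seed layer and seed size,
#' regenerates the synthetic hierarchy once per replicate (so the ensemble
#' averages over both network and dynamical randomness), seeds at random
#' within the layer, runs the dosage model and reports the mean peak
#' adopted fraction.
#'
#' @param topologies character vector from
#'   `c("isolated", "full", "rgg", "ba", "er")`.
#' @param seed_levels `1` (staff) and/or `2` (managers).
#' @param seed_sizes `"minimal"` (1 node) and/or `"community"`
#'   (`round(0.015 N_total)` nodes).
#' @param n_runs replicates per cell.
#' @param base_seed integer; run i of a cell uses master seed
#'   `base_seed + i` offset by a cell index so cells are independent.
#' @param n_staff,k_avg,c_frac synthetic network parameters (defaults
#'   1000, 20, 0.06).
#' @param manager_k mean degree for rgg/ba manager layers and the mean
#'   degree an er layer is parameterized to (`p = manager_k / (c - 1)`).
#' @param params a [dosage_params()] object.
#' @return data.frame with one row per cell: topology, seed level, seed
#'   size, mean/sd/se of the peak adopted fraction, replicate count.
#' @export
table2_experiment <- function(topologies = c("isolated", "full", "rgg",
                                             "ba", "er"),
                              seed_levels = c(1L, 2L),
                              seed_sizes = c("minimal", "community"),
                              n_runs = 300L, base_seed = 1L,
                              n_staff = 1000L, k_avg = 20, c_frac = 0.06,
                              manager_k = 20, params = dosage_params()) {
  cells <- expand.grid(topology = topologies, seed_level = seed_levels,
                       seed_size = seed_sizes, stringsAsFactors = FALSE)
  cc <- round(c_frac * n_staff)
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    kp <- if (cell$topology == "er") manager_k / (cc - 1) else manager_k
    imax <- numeric(n_runs)
    for (i in seq_len(n_runs)) {
      seed_i <- as.integer(base_seed) + (ci - 1L) * n_runs + i
      h <- build_synthetic_hierarchy(n_staff, k_avg, c_frac,
                                     manager_topology = cell$topology,
                                     manager_k_or_p = kp, rng_seed = seed_i)
      count <- if (cell$seed_size == "minimal") 1L else
        community_seed_count(h$graph)
      seeds <- select_seeds(h$graph,
                            seed_spec("random", level = cell$seed_level,
                                      count = count),
                            rng_seed = seed_i)
      run <- run_dosage(h$graph, params, seeds, master_seed = seed_i)
      imax[i] <- max_adoption(run)
    }
    out[[ci]] <- data.frame(topology = cell$topology,
                            seed_level = cell$seed_level,
                            seed_size = cell$seed_size,
                            imax_mean = mean(imax), imax_sd = stats::sd(imax),
                            imax_se = stats::sd(imax) / sqrt(n_runs),
                            n_runs = n_runs)
  }
  do.call(rbind, out)
}

#' Peak adoption versus manager connection density
#'
#' Sweeps the Erdos-Renyi manager-layer connection probability at fixed
#' system size and reports the mean peak adopted fraction per probability,
#' for a given seed layer and size.
#'
#' @param p_grid ER connection probabilities.
#' @param seed_level seed layer (1 staff, 2 managers).
#' @param seed_size `"minimal"` or `"community"`.
#' @param n_runs replicates per grid point.
#' @param base_seed integer seed base.
#' @param n_staff,k_avg,c_frac network parameters.
#' @param params a [dosage_params()] object.
#' @return data.frame with columns `p`, `imax_mean`, `imax_sd`, `imax_se`.
#' @export
sweep_manager_density <- function(p_grid, seed_level = 2L,
                                  seed_size = "community", n_runs = 200L,
                                  base_seed = 1L, n_staff = 1000L,
                                  k_avg = 20, c_frac = 0.06,
                                  params = dosage_params()) {
  out <- vector("list", length(p_grid))
  for (gi in seq_along(p_grid)) {
    p <- p_grid[gi]
    topo <- if (p <= 0) "isolated" else "er"
    imax <- numeric(n_runs)
    for (i in seq_len(n_runs)) {
      seed_i <- as.integer(base_seed) + (gi - 1L) * n_runs + i
      h <- build_synthetic_hierarchy(n_staff, k_avg, c_frac,
                                     manager_topology = topo,
                                     manager_k_or_p = p, rng_seed = seed_i)
      count <- if (seed_size == "minimal") 1L else
        community_seed_count(h$graph)
      seeds <- select_seeds(h$graph,
                            seed_spec("random", level = seed_level,
                                      count = count), rng_seed = seed_i)
      imax[i] <- max_adoption(run_dosage(h$graph, params, seeds, seed_i))
    }
    out[[gi]] <- data.frame(p = p, imax_mean = mean(imax),
                            imax_sd = stats::sd(imax),
                            imax_se = stats::sd(imax) / sqrt(n_runs))
  }
  do.call(rbind, out)
}

#' Peak adoption versus system size
#'
#' Sweeps the staff-layer size with minimal (unconnected) manager wiring,
#' `c = 0.06 N` managers and a 1.5% random staff seed, reporting the mean
#' peak adopted fraction per size.
#'
#' @param n_grid staff-layer sizes.
#' @param n_runs replicates per size.
#' @param base_seed integer seed base.
#' @param k_avg,c_frac network parameters.
#' @param params a [dosage_params()] object.
#' @return data.frame with columns `n_staff`, `imax_mean`, `imax_sd`,
#'   `imax_se`.
#' @export
sweep_system_size <- function(n_grid, n_runs = 200L, base_seed = 1L,
                              k_avg = 20, c_frac = 0.06,
                              params = dosage_params()) {
  out <- vector("list", length(n_grid))
  for (gi in seq_along(n_grid)) {
    n_staff <- n_grid[gi]
    imax <- numeric(n_runs)
    for (i in seq_len(n_runs)) {
      seed_i <- as.integer(base_seed) + (gi - 1L) * n_runs + i
      h <- build_synthetic_hierarchy(n_staff, k_avg, c_frac,
                                     manager_topology = "isolated",
                                     rng_seed = seed_i)
      seeds <- select_seeds(h$graph,
                            seed_spec("random", level = 1L,
                                      count = community_seed_count(h$graph)),
                            rng_seed = seed_i)
      imax[i] <- max_adoption(run_dosage(h$graph, params, seeds, seed_i))
    }
    out[[gi]] <- data.frame(n_staff = n_staff, imax_mean = mean(imax),
                            imax_sd = stats::sd(imax),
                            imax_se = stats::sd(imax) / sqrt(n_runs))
  }
  do.call(rbind, out)
}

#' Seed-strategy grid on a fixed network
#'
#' Runs a full grid over seeding strategies, seed layers, seed sizes and
#' hierarchical versus flat (override off) dynamics on one fixed graph,
#' with common master seeds across every cell so that differences are
#' paired (common random numbers).
#'
#' @param graph a layered graph.
#' @param strategies subset of `c("random", "degree", "voterank", "onion")`.
#' @param levels seed layers (integers and/or `"all"`).
#' @param counts seed counts.
#' @param modes subset of `c("hierarchical", "flat")`.
#' @param n_runs replicates per cell.
#' @param base_seed integer; master seeds `base_seed + 1:n_runs` are shared
#'   across cells.
#' @param params a [dosage_params()] object (its `manager_override` field
#'   is overridden per mode).
#' @return data.frame with one row per cell and the mean/sd/se of the peak
#'   adopted fraction.
#' @export
run_seed_grid <- function(graph, strategies = "random", levels = 1L,
                          counts = 1L, modes = "hierarchical",
                          n_runs = 100L, base_seed = 1L,
                          params = dosage_params()) {
  validate_layered_graph(graph)
  cells <- expand.grid(strategy = strategies, level = levels, count = counts,
                       mode = modes, stringsAsFactors = FALSE)
  master_seeds <- as.double(base_seed) + seq_len(n_runs)
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    p <- params
    p$manager_override <- cell$mode == "hierarchical"
    ens <- run_ensemble(graph, p,
                        seed_spec(cell$strategy, cell$level,
                                  as.integer(cell$count)),
                        n_runs = n_runs, master_seeds = master_seeds)
    out[[ci]] <- data.frame(strategy = cell$strategy, level = cell$level,
                            count = cell$count, mode = cell$mode,
                            imax_mean = mean(ens$imax),
                            imax_sd = stats::sd(ens$imax),
                            imax_se = stats::sd(ens$imax) / sqrt(n_runs),
                            n_runs = n_runs)
  }
  do.call(rbind, out)
}
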