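#' Dosage model parameters
#'
#' Bundles the constants of the dose-memory contagion model.  Each node
#' carries an adoption threshold `d* ~ N(threshold_mean, threshold_sd)`
#' resampled to be strictly positive, and a rolling memory of its last `T`
#' received doses.  An infected speaker confers a dose
#' `~ N(dose_mean, dose_sd)` resampled to be non-negative; a susceptible or
#' removed speaker confers a zero dose.  A susceptible listener whose
#' cumulative dose `D` (sum over the memory window) reaches its threshold
#' adopts (`S -> I`); an adopted listener with `D` below threshold abandons
#' with probability `r` per activation (`I -> R`, absorbing).  With the
#' hierarchical override on, an infected speaker one or more levels above
#' its listener confers a dose equal to the listener's threshold, which
#' guarantees an immediate switch; turning the override off gives the flat
#' (monoplex) ablation.  `si_mode` forces `r = 0`, reducing the dynamics to
#' an SI process whose only absorbing state on a connected graph is full
#' consensus.
#'
#' Defaults follow the model's standard parameterization: `T = 5`,
#' `r = 1/T = 0.2`, thresholds `N(1, 0.5)`, doses
#' `N(0.5 <d*>, 0.25 <d*>) = N(0.5, 0.25)` with the nominal threshold mean
#' `<d*> = 1`.
#'
#' @param T memory window length, in interactions (default 5).
#' @param r removal probability per eligible activation (default `1/T`).
#' @param threshold_mean,threshold_sd threshold distribution (default 1, 0.5).
#' @param dose_mean,dose_sd dose distribution (default 0.5, 0.25).
#' @param manager_override logical; hierarchical dose override (default TRUE).
#' @param si_mode logical; force `r = 0` (default FALSE).
#' @param max_micro_steps run-length cap in micro-steps (default 1e6).
#' @param early_stop_on_extinction stop once no further transition is
#'   possible: no adopted nodes remain, or an `si_mode` run reaches full
#'   consensus (default TRUE).
#' @return an object of class `dosage_params`.
#' @export
dosage_params <- function(T = 5L, r = 1 / T, threshold_mean = 1,
                          threshold_sd = 0.5, dose_mean = 0.5,
                          dose_sd = 0.25, manager_override = TRUE,
                          si_mode = FALSE, max_micro_steps = 1e6,
                          early_stop_on_extinction = TRUE) {
  stopifnot(T >= 1, r >= 0, r <= 1, threshold_sd >= 0, dose_sd >= 0,
            threshold_mean > 0, max_micro_steps >= 0)
  structure(list(T = as.integer(T), r = r, threshold_mean = threshold_mean,
                 threshold_sd = threshold_sd, dose_mean = dose_mean,
                 dose_sd = dose_sd, manager_override = isTRUE(manager_override),
                 si_mode = isTRUE(si_mode), max_micro_steps = max_micro_steps,
                 early_stop_on_extinction = isTRUE(early_stop_on_extinction)),
            class = "dosage_params")
}

#' @export
print.dosage_params <- function(x, ...) {
  cat("Dosage model parameters\n")
  cat(sprintf("  memory window T = %d, removal rate r = %g%s\n", x$T, x$r,
              if (x$si_mode) " (si_mode: r forced to 0)" else ""))
  cat(sprintf("  thresholds ~ N(%g, %g) truncated > 0\n",
              x$threshold_mean, x$threshold_sd))
  cat(sprintf("  doses      ~ N(%g, %g) truncated >= 0\n",
              x$dose_mean, x$dose_sd))
  cat(sprintf("  manager override: %s; cap %g micro-steps\n",
              if (x$manager_override) "on" else "off (flat network)",
              x$max_micro_steps))
  invisible(x)
}

#' Per-node adoption thresholds for a given master seed
#'
#' Draws the thresholds exactly as a run with the same `master_seed` does:
#' from the dedicated threshold substream, in node-id order, resampling any
#' non-positive draw.  Useful for auditing the common-random-number
#' contract.
#'
#' @param n number of nodes.
#' @param params a [dosage_params()] object.
#' @param master_seed integer master seed.
#' @return numeric vector of `n` strictly positive thresholds.
#' @export
sample_thresholds <- function(n, params = dosage_params(), master_seed) {
  sample_thresholds_cpp(n, params$threshold_mean, params$threshold_sd,
                        as.double(master_seed))
}

# internal: CSR adjacency of a layered graph, 0-based
graph_csr <- function(graph) {
  adj <- igraph::as_adj_list(graph)
  deg <- lengths(adj)
  list(offsets = as.integer(c(0L, cumsum(deg))),
       neighbors = as.integer(unlist(adj, use.names = FALSE)) - 1L)
}

#' Run one realization of the dosage model
#'
#' Simulates up to `params$max_micro_steps` micro-steps (one
#' listener-speaker interaction each) and records the S/I/R counts at every
#' epoch boundary, one epoch being `N` micro-steps, so each node is
#' activated once per epoch in expectation.  All randomness (thresholds,
#' listener choice, speaker choice, doses, removals) derives from
#' `master_seed` through five independent substreams, so a run is exactly
#' reproducible and two graphs on the same node set share attempted
#' transmission pathways under a common seed.
#'
#' @param graph a layered graph.
#' @param params a [dosage_params()] object.
#' @param seeds character vector of node names (or integer vertex indices)
#'   initially in state I.
#' @param master_seed integer master seed for the run.
#' @return an object of class `dosage_run`: a list with `trajectory`
#'   (data.frame of epoch, S, I, R), `n` (node count), `peak_I`,
#'   `peak_epoch` (earliest epoch of the peak concurrent adopted count),
#'   `consensus_epoch` and `extinction_epoch` (NA when not reached),
#'   `consensus_step`/`extinction_step` in micro-steps, and `steps_done`.
#' @examples
#' h <- build_synthetic_hierarchy(200, k_avg = 10, rng_seed = 3)
#' run <- run_dosage(h$graph, dosage_params(), seeds = "1", master_seed = 11)
#' max_adoption(run)
#' @export
run_dosage <- function(graph, params = dosage_params(), seeds,
                       master_seed) {
  validate_layered_graph(graph)
  n <- igraph::vcount(graph)
  if (is.character(seeds)) {
    seed_idx <- match(seeds, igraph::V(graph)$name)
    if (anyNA(seed_idx)) stop("unknown seed node name(s)")
  } else {
    seed_idx <- as.integer(seeds)
    stopifnot(all(seed_idx >= 1L), all(seed_idx <= n))
  }
  csr <- graph_csr(graph)
  res <- dosage_run_cpp(csr$offsets, csr$neighbors, node_levels(graph),
                        seed_idx - 1L, params$T,
                        if (params$si_mode) 0 else params$r,
                        params$threshold_mean, params$threshold_sd,
                        params$dose_mean, params$dose_sd,
                        params$manager_override, params$si_mode,
                        params$max_micro_steps,
                        params$early_stop_on_extinction,
                        as.double(master_seed), FALSE)
  traj <- data.frame(epoch = seq_along(res$S) - 1L, S = res$S, I = res$I,
                     R = res$R)
  structure(list(
    trajectory = traj, n = n, peak_I = res$peak_I,
    peak_epoch = floor(res$peak_step / n),
    consensus_step = if (res$consensus_step < 0) NA_real_ else res$consensus_step,
    extinction_step = if (res$extinct_step < 0) NA_real_ else res$extinct_step,
    consensus_epoch = if (res$consensus_step < 0) NA_real_
                      else floor(res$consensus_step / n),
    extinction_epoch = if (res$extinct_step < 0) NA_real_
                       else floor(res$extinct_step / n),
    steps_done = res$steps_done, params = params, master_seed = master_seed,
    seeds = seed_idx), class = "dosage_run")
}

#' @export
print.dosage_run <- function(x, ...) {
  cat(sprintf("Dosage model run: N = %d, %d seed(s), %g micro-steps\n",
              x$n, length(x$seeds), x$steps_done))
  cat(sprintf("  peak adoption %d/%d (%.3f) at epoch %d\n", x$peak_I, x$n,
              x$peak_I / x$n, x$peak_epoch))
  if (!is.na(x$extinction_epoch)) {
    cat(sprintf("  extinction at epoch %d\n", x$extinction_epoch))
  } else if (!is.na(x$consensus_epoch)) {
    cat(sprintf("  full consensus at epoch %d\n", x$consensus_epoch))
  } else {
    cat("  run ended at the micro-step cap\n")
  }
  invisible(x)
}

#' Seed specification
#'
#' @param strategy one of `"random"`, `"degree"`, `"voterank"`, `"onion"`.
#' @param level integer layer index the seeds must come from, or `"all"`
#'   for no layer restriction.
#' @param count number of seed nodes.
#' @return an object of class `seed_spec`.
#' @seealso [select_seeds()]
#' @export
seed_spec <- function(strategy = "random", level = 1L, count = 1L) {
  strategy <- match.arg(strategy, c("random", "degree", "voterank", "onion"))
  stopifnot(count >= 0)
  structure(list(strategy = strategy, level = level,
                 count = as.integer(count)), class = "seed_spec")
}

#' Run an ensemble of dosage-model replicates
#'
#' Runs `n_runs` independent realizations, one per master seed, and
#' aggregates peak adoption, extinction and consensus times, and the mean
#' S/I/R trajectory (runs that end early are carried forward at their final
#' state, which an extinct SIR run holds forever).  Master seeds must be
#' distinct so that paired common-random-number comparisons across
#' configurations stay valid.  For the `"random"` strategy seeds are
#' redrawn per run from the run's master seed (identical node
#' initialization across compared configurations); deterministic strategies
#' (degree, voterank, onion) are selected once.
#'
#' @param graph a layered graph.
#' @param params a [dosage_params()] object.
#' @param spec a [seed_spec()], or a fixed vector of seed node names used
#'   for every run.
#' @param n_runs number of replicates.
#' @param master_seeds integer vector of length `n_runs`; defaults to
#'   `base_seed + 0:(n_runs-1)`.
#' @param base_seed base for default master seeds.
#' @param keep_trajectories logical; retain every run's trajectory
#'   (memory-heavy, default FALSE keeps only the mean).
#' @return an object of class `dosage_ensemble`: `imax` (per-run peak
#'   adopted fractions), `summary` (data.frame of metric mean/sd/se/n),
#'   `mean_trajectory`, `peak_epochs`, `extinction_epochs`,
#'   `consensus_epochs`, `runs` (if kept), plus the inputs.
#' @examples
#' h <- build_synthetic_hierarchy(200, k_avg = 10, rng_seed = 3)
#' ens <- run_ensemble(h$graph, dosage_params(),
#'                     seed_spec("random", level = 2, count = 3),
#'                     n_runs = 20, base_seed = 100)
#' ens$summary
#' @export
run_ensemble <- function(graph, params = dosage_params(), spec,
                         n_runs = 100L, master_seeds = NULL,
                         base_seed = 1L, keep_trajectories = FALSE) {
  validate_layered_graph(graph)
  if (is.null(master_seeds)) {
    master_seeds <- as.double(base_seed) + seq_len(n_runs) - 1
  }
  stopifnot(length(master_seeds) == n_runs)
  if (anyDuplicated(master_seeds) > 0L) {
    stop("master seeds must be distinct (common-random-number contract)")
  }
  n <- igraph::vcount(graph)

  fixed_seeds <- NULL
  if (inherits(spec, "seed_spec")) {
    if (spec$strategy != "random") {
      fixed_seeds <- select_seeds(graph, spec)
    }
  } else {
    fixed_seeds <- spec
  }

  imax <- numeric(n_runs)
  peak_epochs <- numeric(n_runs)
  ext <- rep(NA_real_, n_runs)
  cons <- rep(NA_real_, n_runs)
  runs <- if (keep_trajectories) vector("list", n_runs) else NULL
  trajs <- vector("list", n_runs)

  for (i in seq_len(n_runs)) {
    seeds_i <- if (is.null(fixed_seeds)) {
      select_seeds(graph, spec, rng_seed = master_seeds[i])
    } else fixed_seeds
    run <- run_dosage(graph, params, seeds_i, master_seeds[i])
    imax[i] <- run$peak_I / n
    peak_epochs[i] <- run$peak_epoch
    ext[i] <- run$extinction_epoch
    cons[i] <- run$consensus_epoch
    trajs[[i]] <- as.matrix(run$trajectory[, c("S", "I", "R")])
    if (keep_trajectories) runs[[i]] <- run
  }

  max_len <- max(vapply(trajs, nrow, 0L))
  traj_sum <- matrix(0, nrow = max_len, ncol = 3)
  for (tr in trajs) {
    if (nrow(tr) < max_len) {
      # an early-ended run holds its final state forever
      tr <- rbind(tr, matrix(rep(tr[nrow(tr), ], max_len - nrow(tr)),
                             ncol = 3, byrow = TRUE))
    }
    traj_sum <- traj_sum + tr
  }
  mean_traj <- data.frame(epoch = seq_len(max_len) - 1L,
                          S = traj_sum[, 1L] / n_runs,
                          I = traj_sum[, 2L] / n_runs,
                          R = traj_sum[, 3L] / n_runs)
  metric_row <- function(name, x) {
    x <- x[!is.na(x)]
    data.frame(metric = name,
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1) stats::sd(x) else NA_real_,
               se = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_,
               n = length(x))
  }
  summary <- rbind(metric_row("imax_fraction", imax),
                   metric_row("peak_epoch", peak_epochs),
                   metric_row("extinction_epoch", ext),
                   metric_row("consensus_epoch", cons))
  structure(list(imax = imax, peak_epochs = peak_epochs,
                 extinction_epochs = ext, consensus_epochs = cons,
                 summary = summary, mean_trajectory = mean_traj,
                 runs = runs, n = n, n_runs = n_runs, params = params,
                 master_seeds = master_seeds, spec = spec),
            class = "dosage_ensemble")
}

#' @export
print.dosage_ensemble <- function(x, ...) {
  cat(sprintf("Dosage model ensemble: %d runs on N = %d\n", x$n_runs, x$n))
  s <- x$summary[x$summary$metric == "imax_fraction", ]
  cat(sprintf("  mean peak adopted fraction %.4f (sd %.4f, se %.4f)\n",
              s$mean, s$sd, s$se))
  invisible(x)
}
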