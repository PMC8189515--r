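test_that("thresholds are positive with truncated-normal moments, reproducibly", {
  n <- 100000
  thr <- sample_thresholds(n, dosage_params(), master_seed = 42)
  expect_true(all(thr > 0))
  # N(1, 0.5) conditioned on > 0: mean 1.0276, sd 0.4707
  expect_lt(abs(mean(thr) - 1.0276), 0.01)
  expect_lt(abs(sd(thr) - 0.4707), 0.01)
  expect_identical(thr, sample_thresholds(n, dosage_params(), master_seed = 42))
  # the run draws the same thresholds from the same master seed: a dyad in
  # which the manager's first downward dose equals the staff threshold
  expect_false(identical(thr[1:10],
                         sample_thresholds(10, dosage_params(), master_seed = 43)))
})

test_that("an all-susceptible population never changes state", {
  g <- clique_graph(10)
  run <- run_dosage(g, dosage_params(max_micro_steps = 5000,
                                     early_stop_on_extinction = FALSE),
                    seeds = character(0), master_seed = 1)
  expect_true(all(run$trajectory$S == 10))
  expect_true(all(run$trajectory$I == 0))
  expect_true(all(run$trajectory$R == 0))
})

test_that("downward dose from an infected manager switches the staff node immediately", {
  # dyad: manager (level 2) seeded, staff susceptible with an enormous
  # threshold that peer doses could never reach; the override must still
  # switch it, and the first-switch time is geometric with p = 1/2
  g <- dyad_graph(levels = c(1L, 2L))
  p <- dosage_params(threshold_mean = 100, threshold_sd = 0, si_mode = TRUE,
                     max_micro_steps = 1e5)
  times <- vapply(1:2000, function(s) {
    run <- run_dosage(g, p, seeds = "b", master_seed = s)
    run$consensus_step
  }, 0)
  expect_true(all(is.finite(times)))  # every staff node adopted
  expect_lt(abs(mean(times) - 2), 4 * sqrt(2) / sqrt(2000))
  # flat ablation: identical graph, override off, peer doses ~ N(0.5, 0.25)
  # can never reach the threshold of 100, so the staff node stays S
  pf <- dosage_params(threshold_mean = 100, threshold_sd = 0, si_mode = TRUE,
                      manager_override = FALSE, max_micro_steps = 2e4)
  runf <- run_dosage(g, pf, seeds = "b", master_seed = 7)
  expect_equal(tail(runf$trajectory$I, 1), 1L)
})

test_that("SI consensus time on a 3-node path matches exact chain enumeration", {
  g <- path_graph(3)
  expected <- si_expected_consensus_steps(g, seed_vertex = 1L)
  expect_equal(expected, 9, tolerance = 1e-10)  # closed form for P3, end seed
  p <- deterministic_params(dose = 2, T = 1L)
  times <- vapply(1:3000, function(s)
    run_dosage(g, p, seeds = "1", master_seed = s)$consensus_step, 0)
  se <- sd(times) / sqrt(length(times))
  expect_lt(abs(mean(times) - expected), 3 * se)
})

test_that("SIR absorption on a dyad matches the analytic take-off probability", {
  # seed a, deterministic dose 2 > threshold 1, T = 1, removal rate r:
  # b adopts before a is removed with probability 1 / (1 + r)
  g <- path_graph(2)
  r <- 0.2
  p <- dosage_params(T = 1L, r = r, threshold_mean = 1, threshold_sd = 0,
                     dose_mean = 2, dose_sd = 0, max_micro_steps = 1e5)
  peaks <- vapply(1:3000, function(s)
    run_dosage(g, p, seeds = "1", master_seed = s)$peak_I, 0L)
  phat <- mean(peaks == 2L)
  p_true <- 1 / (1 + r)
  se <- sqrt(p_true * (1 - p_true) / 3000)
  expect_lt(abs(phat - p_true), 3 * se)
})

test_that("runs conserve S+I+R, R is monotone, and SI-mode I is monotone", {
  h <- build_synthetic_hierarchy(150, k_avg = 10, rng_seed = 4)
  for (s in 1:10) {
    run <- run_dosage(h$graph, dosage_params(max_micro_steps = 5e4),
                      seeds = select_seeds(h$graph, seed_spec("random", 1, 3),
                                           rng_seed = s),
                      master_seed = s)
    tr <- run$trajectory
    expect_true(all(tr$S + tr$I + tr$R == run$n))
    expect_true(all(diff(tr$R) >= 0))
  }
  for (s in 1:5) {
    run <- run_dosage(h$graph, dosage_params(si_mode = TRUE,
                                             max_micro_steps = 5e5),
                      seeds = "1", master_seed = s)
    expect_true(all(diff(run$trajectory$I) >= 0))
    # on a connected graph the only absorbing SI state is full consensus
    expect_equal(tail(run$trajectory$I, 1), run$n)
  }
})

test_that("with r > 0 every run goes extinct in finite time", {
  g <- clique_graph(12)
  for (s in 1:10) {
    run <- run_dosage(g, dosage_params(max_micro_steps = 2e6), seeds = "1",
                      master_seed = s)
    expect_false(is.na(run$extinction_epoch))
    expect_equal(tail(run$trajectory$I, 1), 0L)
  }
})

test_that("runs and ensembles are bit-identical under a fixed master seed", {
  h <- build_synthetic_hierarchy(120, k_avg = 10, rng_seed = 8)
  r1 <- run_dosage(h$graph, dosage_params(), seeds = "5", master_seed = 99)
  r2 <- run_dosage(h$graph, dosage_params(), seeds = "5", master_seed = 99)
  expect_identical(r1$trajectory, r2$trajectory)
  e1 <- run_ensemble(h$graph, dosage_params(), seed_spec("random", 1, 2),
                     n_runs = 10, base_seed = 50)
  e2 <- run_ensemble(h$graph, dosage_params(), seed_spec("random", 1, 2),
                     n_runs = 10, base_seed = 50)
  expect_identical(e1$imax, e2$imax)
  expect_identical(e1$mean_trajectory, e2$mean_trajectory)
  expect_error(run_ensemble(h$graph, dosage_params(), seed_spec("random", 1, 1),
                            n_runs = 2, master_seeds = c(3, 3)),
               "distinct")
})

test_that("hierarchical override dominates the flat ablation under common random numbers", {
  h <- build_synthetic_hierarchy(300, k_avg = 12, rng_seed = 2)
  seeds_fixed <- select_seeds(h$graph, seed_spec("random", 2, 2), rng_seed = 1)
  master <- 1:120
  p_h <- dosage_params(manager_override = TRUE)
  p_f <- dosage_params(manager_override = FALSE)
  imax_h <- run_ensemble(h$graph, p_h, seeds_fixed, n_runs = 120,
                         master_seeds = master)$imax
  imax_f <- run_ensemble(h$graph, p_f, seeds_fixed, n_runs = 120,
                         master_seeds = master)$imax
  expect_gt(mean(imax_h - imax_f), 0)
})

test_that("seed nodes start with empty memory and can be removed at once", {
  # a single isolated seed receives only null doses; with r = 1 it is
  # removed on its first activation, so extinction is immediate
  g <- igraph::set_vertex_attr(
    igraph::set_vertex_attr(igraph::make_empty_graph(1, directed = FALSE),
                            "name", value = "a"),
    "level", value = 1L)
  run <- run_dosage(g, dosage_params(T = 1L, r = 1, max_micro_steps = 100),
                    seeds = "a", master_seed = 3)
  expect_equal(run$extinction_step, 1)
})
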