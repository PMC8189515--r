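test_that("RGG realized mean degree matches the boundary-corrected expectation", {
  n <- 1000
  k <- 20
  r <- sqrt(k / (n * pi))
  # expected disc-in-square area: pi r^2 - (8/3) r^3 + r^4 / 2
  k_expected <- (n - 1) * (pi * r^2 - (8 / 3) * r^3 + r^4 / 2)
  degs <- vapply(1:20, function(s) mean(igraph::degree(make_base_rgg(n, k, s))), 0)
  expect_lt(abs(mean(degs) - k_expected), 0.5)
  # the bulk-density radius formula lands near the requested degree
  expect_lt(abs(mean(degs) - k) / k, 0.10)
})

test_that("RGG edge rule is inclusive at the radius and rejects degenerate radii", {
  coords <- rbind(c(0, 0), c(0.3, 0), c(0.8, 0))
  g <- rgg_from_coords(coords, radius = 0.3)
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 1L)  # exactly the pair at distance == 0.3
  expect_setequal(as.vector(el), c("1", "2"))
  expect_error(make_base_rgg(2, k_avg = 2 * 2 * pi, rng_seed = 1),
               "radius")
})

test_that("fluid partition covers the base layer with exactly c communities", {
  g <- make_base_rgg(300, 10, rng_seed = 5)
  expect_true(igraph::is_connected(g))
  p <- partition_fluid(g, 20, rng_seed = 1)
  expect_length(p, 300)
  expect_equal(sort(unique(p)), 1:20)
  expect_equal(mean(tabulate(p, 20)), 300 / 20)
  expect_equal(unique(partition_fluid(g, 1, rng_seed = 1)), 1L)
  expect_equal(sort(partition_fluid(g, 300, rng_seed = 1)), 1:300)
})

test_that("management layer wiring follows the requested topology", {
  g <- make_base_rgg(300, 12, rng_seed = 11)
  expect_true(igraph::is_connected(g))
  cc <- 18
  p <- partition_fluid(g, cc, rng_seed = 2)

  iso <- attach_management_layer(g, p, "isolated")
  lv <- node_levels(iso)
  intra2 <- sum(is_intra_edge(iso) &
                  lv[igraph::as_edgelist(iso, names = FALSE)[, 1]] == 2L)
  expect_equal(intra2, 0L)
  # every staff node has exactly one manager neighbour, and each manager's
  # inter-layer degree is its community size
  el <- igraph::as_edgelist(iso, names = FALSE)
  inter <- el[lv[el[, 1]] != lv[el[, 2]], , drop = FALSE]
  staff_up <- tabulate(ifelse(lv[inter[, 1]] == 1L, inter[, 1], inter[, 2]), 300)
  expect_true(all(staff_up == 1L))
  mgr_down <- table(ifelse(lv[inter[, 1]] == 2L, inter[, 1], inter[, 2]))
  expect_equal(unname(sort(as.integer(mgr_down))),
               unname(sort(tabulate(p, cc))))

  full <- attach_management_layer(g, p, "full")
  expect_equal(igraph::ecount(full) - igraph::ecount(iso), cc * (cc - 1) / 2)

  expect_error(attach_management_layer(g, p, "er", manager_k_or_p = 1.5),
               "probability")
})

test_that("ER manager wiring hits the analytic mean degree p*(c-1)", {
  g <- make_base_rgg(200, 10, rng_seed = 23)
  expect_true(igraph::is_connected(g))
  cc <- 60
  p_conn <- 20 / 59
  part <- rep_len(1:cc, 200)  # any covering partition works for the wiring
  degs <- vapply(1:50, function(s) {
    h <- attach_management_layer(g, part, "er", p_conn, rng_seed = s)
    lv <- node_levels(h)
    intra <- is_intra_edge(h)
    el <- igraph::as_edgelist(h, names = FALSE)
    mgr_edges <- sum(intra & lv[el[, 1]] == 2L)
    2 * mgr_edges / cc
  }, 0)
  expected <- p_conn * (cc - 1)
  # mean degree per draw is 2 Bin(c(c-1)/2, p) / c
  se <- sqrt(2 * (cc - 1) * p_conn * (1 - p_conn) / (cc * 50))
  expect_lt(abs(mean(degs) - expected), 4 * se)
})

test_that("synthetic hierarchy has round(c_frac * n) managers and is seed-reproducible", {
  h <- build_synthetic_hierarchy(500, k_avg = 15, c_frac = 0.06, rng_seed = 9)
  sizes <- layer_sizes(h$graph)
  expect_equal(unname(sizes["2"]), 30L)
  expect_equal(sum(sizes), 530L)
  expect_equal(sum(tabulate(h$partition)), 500L)

  h2 <- build_synthetic_hierarchy(500, k_avg = 15, c_frac = 0.06, rng_seed = 9)
  expect_identical(igraph::as_edgelist(h$graph), igraph::as_edgelist(h2$graph))
  expect_identical(h$partition, h2$partition)
})
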