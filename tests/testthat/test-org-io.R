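test_that("org-network CSVs round-trip through write and read", {
  h <- build_synthetic_hierarchy(120, k_avg = 8, rng_seed = 13)
  nf <- withr::local_tempfile(fileext = ".csv")
  ef <- withr::local_tempfile(fileext = ".csv")
  write_org_network(h$graph, nf, ef)
  g2 <- read_org_network(nf, ef)
  expect_setequal(igraph::V(g2)$name, igraph::V(h$graph)$name)
  key <- function(g) {
    el <- igraph::as_edgelist(g)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_identical(key(g2), key(h$graph))
  expect_identical(node_levels(g2)[match(igraph::V(h$graph)$name,
                                         igraph::V(g2)$name)],
                   node_levels(h$graph))
})

test_that("the reader rejects malformed input and accepts empty edge lists", {
  nf <- withr::local_tempfile(fileext = ".csv")
  ef <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("node_id,level", "1,1", "2,1"), nf)
  writeLines(c("source,target", "1,3"), ef)
  expect_error(read_org_network(nf, ef), "absent")
  writeLines(c("source,target"), ef)
  g <- read_org_network(nf, ef)
  expect_equal(igraph::vcount(g), 2L)
  expect_equal(igraph::ecount(g), 0L)
  writeLines(c("node_id,level", "1,1", "1,2"), nf)
  expect_error(read_org_network(nf, ef), "duplicate")
})

test_that("weighted-edge thresholding is strictly greater-than", {
  rec <- data.frame(source = c("a", "a", "b"), target = c("b", "c", "c"),
                    weight = c(369, 370, 371))
  kept <- threshold_weighted_edges(rec, 370)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$weight, 371)
  expect_equal(nrow(threshold_weighted_edges(rec, 0)), 3L)
  # threshold chosen to match a target mean degree reproduces it to within
  # one edge-removal step
  set.seed(1)
  n <- 40
  pairs <- t(combn(n, 2))
  rec2 <- data.frame(source = pairs[, 1], target = pairs[, 2],
                     weight = rexp(nrow(pairs), rate = 1 / 100))
  th <- choose_weight_threshold(rec2, k_target = 6, n_nodes = n)
  surviving <- sum(rec2$weight > th)
  expect_lt(abs(surviving - 6 * n / 2), 1.5)
})

test_that("layer statistics recover closed forms on cliques and paths", {
  cl <- layer_stats(clique_graph(5))
  tot <- cl[cl$layer == "Total", ]
  expect_equal(tot$degree, 4)
  expect_equal(tot$clustering, 1)
  expect_equal(tot$closeness, 1)

  p3 <- layer_stats(path_graph(3))
  tot3 <- p3[p3$layer == "Total", ]
  # closeness: centre 1, ends 2/3
  expect_equal(tot3$closeness, (1 + 2 / 3 + 2 / 3) / 3)
  expect_equal(tot3$clustering, 0)
  expect_true(attr(p3, "connected"))
})

test_that("line-org fixture is a clique-per-department tree with one apex", {
  g <- make_lineorg_fixture(c(8, 2), dept_size_mean = 6, rng_seed = 3)
  lv <- node_levels(g)
  expect_equal(max(lv), 4L)
  expect_equal(sum(lv == 4L), 1L)
  expect_true(igraph::is_connected(g))
  # every non-apex node has exactly one upward inter-layer edge
  el <- igraph::as_edgelist(g, names = FALSE)
  up <- integer(igraph::vcount(g))
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1]; b <- el[i, 2]
    if (lv[a] < lv[b]) up[a] <- up[a] + 1L
    if (lv[b] < lv[a]) up[b] <- up[b] + 1L
  }
  expect_true(all(up[lv < 4L] == 1L))
  # staff in a department of size >= 3 sit in a clique: local clustering 1
  # among their intra-layer neighbourhood, so base-layer clustering is high
  st <- layer_stats(g)
  base_clust <- st$clustering[st$layer == "1"]
  expect_gt(base_clust, 0.8)
})

test_that("line-org fixture at the standard shape lands near mean degree 20", {
  g <- make_lineorg_fixture(c(60, 12, 3), dept_size_mean = 16.7, rng_seed = 1)
  k <- mean(igraph::degree(g))
  expect_lt(abs(k - 20) / 20, 0.15)
})

test_that("project fixture is hub-skewed with managers as the major hub", {
  g <- make_project_fixture(c(20, 4), dept_size_mean = 12, k_avg = 14,
                            rng_seed = 5)
  lv <- node_levels(g)
  deg <- igraph::degree(g)
  expect_gt(mean(deg[lv == 2]), mean(deg[lv == 1]))
  expect_lt(abs(mean(deg) - 14) / 14, 0.10)
  # the manager tree guarantees no isolated staff
  expect_true(all(deg >= 1))
  expect_true(igraph::is_connected(g))
})
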