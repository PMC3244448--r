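test_that("betweenness matches analytic values on path and star graphs", {
  g <- path_graph(c("a", "b", "c", "d", "e"))
  bc <- node_betweenness(g)
  expect_equal(unname(bc["c"]), 4)
  expect_equal(unname(bc["b"]), 3)
  expect_equal(unname(bc["a"]), 0)
  star <- star_graph("hub", sprintf("l%d", 1:7))
  expect_equal(unname(node_betweenness(star)["hub"]), 7 * 6 / 2)
})

test_that("betweenness equals the exhaustive shortest-path oracle on random graphs", {
  for (seed in 1:12) {
    rg <- random_edge_matrix(sample(6:10, 1), 0.35, seed)
    if (is.null(rg$edges)) next
    g <- as_interactome(rg$edges, nodes = rg$nodes)
    adj <- bf_adjacency(rg$edges, rg$nodes)
    bc <- node_betweenness(g)
    oracle <- bf_betweenness(adj)
    expect_equal(bc[sort(names(bc))], oracle[sort(names(oracle))],
                 tolerance = 1e-10)
  }
})

test_that("randomization preserves every degree and is seed-deterministic", {
  g <- generate_interactome(80, 2, seed = 19)
  r1 <- rewire_degree_preserving(g, swaps_per_edge = 5, seed = 99)
  r2 <- rewire_degree_preserving(g, swaps_per_edge = 5, seed = 99)
  expect_identical(spanet:::edge_keys(r1), spanet:::edge_keys(r2))
  expect_false(identical(spanet:::edge_keys(r1), spanet:::edge_keys(g)))
  expect_identical(igraph::degree(r1)[igraph::V(g)$name],
                   igraph::degree(g)[igraph::V(g)$name])
  expect_false(igraph::any_multiple(r1))
  expect_false(igraph::any_loop(r1))
})

test_that("a triangle admits no valid swap and is returned unchanged with a warning", {
  tri <- complete_graph(c("A", "B", "C"))
  expect_warning(out <- rewire_degree_preserving(tri, seed = 1,
                                                 max_tries_factor = 2),
                 "no valid")
  expect_identical(spanet:::edge_keys(out), spanet:::edge_keys(tri))
  expect_error(rewire_degree_preserving(path_graph(c("a", "b")), seed = 1),
               class = "spanet_parameter_error")
})

test_that("the significance test handles degenerate and extreme cases as specified", {
  # permanent leaf: identical zero betweenness everywhere -> discard
  st <- significance_test(0, rep(0, 100), alpha = 0.001)
  expect_equal(st$p, 1)
  expect_false(st$keep)
  # zero spread, nonzero separation -> p = 0 -> keep
  st2 <- significance_test(10, rep(2, 100), alpha = 0.001)
  expect_equal(st2$p, 0)
  expect_true(st2$keep)
  # large separation with spread -> keep
  set.seed(5)
  st3 <- significance_test(1000, rnorm(100, 5, 1), alpha = 0.001)
  expect_lt(st3$p, 0.001)
  expect_error(significance_test(1, c(2), alpha = 0.01),
               class = "spanet_parameter_error")
})

test_that("the control chart flags ensemble members far from the reference skewness", {
  set.seed(11)
  ref <- rexp(200)                       # skewed reference
  nulls <- replicate(30, rexp(200), simplify = FALSE)
  ch <- control_chart(nulls, ref)
  expect_false(any(ch$flagged))
  nulls[[7]] <- c(rep(0, 199), 1e6)      # extreme skewness
  ch2 <- control_chart(nulls, ref)
  expect_true(ch2$flagged[7])
  expect_equal(ch2$cl, spanet:::sample_skewness(ref))
})

test_that("tuning output is deterministic, nested in the original, and alpha-monotone", {
  g <- generate_interactome(60, 2, seed = 23)
  t1 <- tune_network(g, alpha = 0.01, n_random = 25, swaps_per_edge = 5,
                     seed = 7)
  t2 <- tune_network(g, alpha = 0.01, n_random = 25, swaps_per_edge = 5,
                     seed = 7)
  expect_identical(t1$report, t2$report)
  expect_true(all(igraph::V(t1$network)$name %in% igraph::V(g)$name))
  expect_true(all(spanet:::edge_keys(t1$network) %in% spanet:::edge_keys(g)))
  # p-values are shared across alphas, so discard sets nest
  discards <- lapply(c(0.001, 0.01, 0.1), function(a) {
    t1$report$protein[!(t1$report$p < a)]
  })
  expect_true(all(discards[[3]] %in% discards[[2]]))
  expect_true(all(discards[[2]] %in% discards[[1]]))
  # alpha = 1 removes exactly the all-differences-zero nodes
  t_all <- tune_network(g, alpha = 1, n_random = 25, swaps_per_edge = 5,
                        seed = 7)
  removed <- setdiff(igraph::V(g)$name, igraph::V(t_all$network)$name)
  zero_diff <- t_all$report$protein[t_all$report$p == 1]
  expect_setequal(removed, zero_diff)
})

test_that("protected proteins survive tuning and a cut-vertex is kept", {
  # two dense cliques joined by a single bridge node: all shortest paths
  # between the cliques cross the bridge, which rewiring destroys
  left <- t(utils::combn(sprintf("L%d", 1:6), 2))
  right <- t(utils::combn(sprintf("R%d", 1:6), 2))
  bridge <- rbind(c("L1", "XB"), c("XB", "R1"))
  g <- as_interactome(rbind(left, right, bridge))
  # the clique-pair graph has so few rewirable configurations that the
  # skewness ensemble collapses; the chart is not informative here
  tn <- tune_network(g, alpha = 0.01, n_random = 30, swaps_per_edge = 5,
                     seed = 2, use_control_chart = FALSE)
  expect_true("XB" %in% igraph::V(tn$network)$name)
  tn2 <- tune_network(g, alpha = 1e-12, n_random = 30, swaps_per_edge = 5,
                      seed = 2, protect = c("L3", "R4"),
                      use_control_chart = FALSE)
  expect_true(all(c("L3", "R4") %in% igraph::V(tn2$network)$name))
})
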