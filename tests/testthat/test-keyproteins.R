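# frequencies that land m = c(30, 6, 1, 1, 1, 1) in k = 6 equal-width bins
# over (0, 96]: widths of 16
worked_frequencies <- function() {
  f <- c(seq(2, 15, length.out = 30),   # bin 1: (0, 16]
         seq(18, 31, length.out = 6),   # bin 2: (16, 32]
         40, 60, 70, 96)                # bins 3, 4, 5, 6
  names(f) <- sprintf("prot%02d", seq_along(f))
  f
}

test_that("the 40-protein worked example reproduces every decomposition quantity", {
  d <- decompose_participation(worked_frequencies())
  expect_equal(d$n, 40L)
  expect_equal(d$k, 6L)
  expect_equal(d$m, c(30, 6, 1, 1, 1, 1))
  expect_equal(d$M, c(75, 90, 92.5, 95, 97.5, 100))
  expect_equal(d$D, c(75, 15, 2.5, 2.5, 2.5, 2.5))
  expect_equal(d$fold_change, c(5, 6, 1, 1, 1))
  expect_equal(d$threshold_bin, 2L)
  expect_false(d$fallback)
  # key set: the 4 proteins above bin 2's upper edge, 10% of 40 exactly
  expect_setequal(d$keys, c("prot37", "prot38", "prot39", "prot40"))
})

test_that("degenerate histograms take the flagged fallback path", {
  # n = 4: one protein in the upper bin is 25% > 10%, floor(0.4) = 0 keys
  f4 <- c(a = 10, b = 12, c = 14, d = 95)
  d4 <- decompose_participation(f4)
  expect_equal(d4$k, 2L)
  expect_equal(d4$m, c(3, 1))
  expect_equal(d4$fold_change, 3)
  expect_true(d4$fallback)
  expect_length(d4$keys, 0L)
  # uniform frequencies: single occupied bin, no ranking signal
  fu <- stats::setNames(rep(40, 9), letters[1:9])
  du <- decompose_participation(fu)
  expect_true(du$fallback)
  expect_error(decompose_participation(numeric()),
               class = "spanet_parameter_error")
  expect_error(decompose_participation(c(a = 0, b = 5)),
               class = "spanet_parameter_error")
})

test_that("the key set depends only on the rank-and-bin structure (scale invariance)", {
  f <- worked_frequencies()
  for (s in c(0.25, 0.5, 0.8)) {
    d <- decompose_participation(f * s)
    expect_setequal(d$keys, decompose_participation(f)$keys)
  }
  # determinism: identical inputs give identical outputs
  expect_identical(decompose_participation(f), decompose_participation(f))
})

test_that("both fold-change readings are available and differ where expected", {
  f <- worked_frequencies()
  d_decay <- decompose_participation(f, fold = "decay")
  d_growth <- decompose_participation(f, fold = "growth")
  expect_equal(d_growth$fold_change, 1 / d_decay$fold_change)
})

test_that("stepwise extraction recovers planted backbones with decoy corridors", {
  for (width in 2:3) {
    for (seed in c(1, 5)) {
      g <- generate_interactome(150, 2, seed = seed)
      pr <- find_far_pair(g, 6)
      pb <- plant_backbone(g, pr[1], pr[2], L = 6, corridor_width = width)
      sp <- enumerate_paths(pb$graph, pr[1], pr[2], L = 6)
      # the corridor is the only length-6 channel: analytic path count
      expect_equal(nrow(sp$paths), 1 + 4 * width + 3 * width^2)
      sk <- stepwise_keys(sp)
      for (s in seq_along(sk$keys)) {
        b <- pb$truth$backbone[[as.character(s + 1L)]]
        expect_true(b %in% sk$keys[[s]])
      }
      expect_true(all(diff(c(nrow(sp$paths), sk$subset_sizes)) <= 0))
    }
  }
})

test_that("a single-path spectrum degenerates gracefully with subset size 1 throughout", {
  g <- path_graph(sprintf("q%d", 1:6))
  sp <- enumerate_paths(g, "q1", "q6", L = 6)
  expect_equal(nrow(sp$paths), 1L)
  sk <- stepwise_keys(sp)
  expect_equal(sk$subset_sizes, rep(1L, 4L))
  expect_length(sk$degenerate_steps, 4L)
  expect_identical(unlist(sk$keys), c("q2", "q3", "q4", "q5"))
})

test_that("global importants exclude endpoints and point at planted backbones", {
  g <- generate_interactome(150, 2, seed = 8)
  pr <- find_far_pair(g, 6)
  pb <- plant_backbone(g, pr[1], pr[2], L = 6, corridor_width = 3)
  sp <- enumerate_paths(pb$graph, pr[1], pr[2], L = 6)
  gi <- global_importants(sp)
  bb <- unlist(pb$truth$backbone)
  expect_false(any(pr %in% gi))
  expect_gt(length(gi), 0L)
  expect_true(all(gi %in% c(bb, unlist(pb$truth$decoys))))
  expect_true(any(bb %in% gi))
  gi_top <- global_importants(sp, method = "top-fraction", fraction = 0.1)
  expect_false(any(pr %in% gi_top))
  expect_true(all(gi_top %in% bb))  # backbones lead the participation ranking
})

test_that("heart networks pool keys with endpoints and report path coverage", {
  g <- generate_interactome(120, 2, seed = 16)
  nodes <- igraph::V(g)$name
  pb <- plant_backbone(g, nodes[1], nodes[4], L = 6, corridor_width = 2)
  sp <- enumerate_paths(pb$graph, nodes[1], nodes[4], L = 6)
  sk <- stepwise_keys(sp)
  heart <- assemble_heart(list(sk), inputs = nodes[1], outputs = nodes[4],
                          g = pb$graph, spectra = list(sp))
  expect_true(all(c(nodes[1], nodes[4]) %in% heart$members))
  expect_true(all(heart$members %in% igraph::V(pb$graph)$name))
  # coverage equals the brute-force classification of fully-covered paths
  inter <- sp$paths[, 2:5, drop = FALSE]
  want <- 100 * mean(apply(inter, 1L, function(r) all(r %in% heart$members)))
  expect_equal(heart$coverage$coverage_pct, want)
  # member set = whole graph covers everything
  all_keys <- sk
  all_keys$keys <- list(igraph::V(pb$graph)$name)
  full <- assemble_heart(list(all_keys), nodes[1], nodes[4], pb$graph,
                         spectra = list(sp))
  expect_equal(full$coverage$coverage_pct, 100)
})
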