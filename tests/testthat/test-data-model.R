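test_that("BioGRID-style loading filters genetic rows, self-loops and duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "Official Symbol Interactor A\tOfficial Symbol Interactor B\tExperimental System Type",
    "A\tB\tphysical",
    "A\tA\tphysical",
    "A\tB\tgenetic",
    "B\tA\tphysical"
  ), path)
  g <- read_interactions(path, quiet = TRUE)
  expect_setequal(igraph::V(g)$name, c("A", "B"))
  expect_equal(igraph::ecount(g), 1L)
  s <- attr(g, "load_summary")
  expect_equal(s$dropped_nonphysical, 1L)
  expect_equal(s$dropped_self, 1L)
  expect_equal(s$dropped_duplicate, 1L)

  g2 <- read_interactions(path, physical_only = FALSE, quiet = TRUE)
  expect_equal(igraph::ecount(g2), 1L)  # genetic row duplicates A-B
})

test_that("bare two-column edge lists load as-is and row order is irrelevant", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rows <- c("A\tB", "C\tD", "E\tF", "G\tH")
  writeLines(rows, path)
  g <- read_interactions(path, quiet = TRUE)
  expect_equal(igraph::ecount(g), 4L)
  writeLines(rev(rep(rows, 2L)), path)  # duplicated, reordered
  g2 <- read_interactions(path, quiet = TRUE)
  expect_identical(spanet:::edge_keys(g), spanet:::edge_keys(g2))
})

test_that("format errors name the problem", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Official Symbol Interactor A\tExperimental System Type",
               "A\tphysical"), path)
  expect_error(read_interactions(path, quiet = TRUE),
               "interactor b", class = "spanet_format_error")
  writeLines(c("Official Symbol Interactor A\tOfficial Symbol Interactor B\tExperimental System Type",
               "A\tB\tgenetic"), path)
  expect_error(read_interactions(path, quiet = TRUE),
               class = "spanet_empty_error")
})

test_that("network round trip is the identity for TSV and GraphML", {
  g <- generate_interactome(100, attachment = 2, seed = 42)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(g, tsv)
  write_network(g, gml, format = "graphml")
  g_tsv <- read_interactions(tsv, quiet = TRUE)
  g_gml <- as_interactome(igraph::read_graph(gml, format = "graphml"))
  for (h in list(g_tsv, g_gml)) {
    expect_setequal(igraph::V(h)$name, igraph::V(g)$name)
    expect_identical(spanet:::edge_keys(h), spanet:::edge_keys(g))
  }
  # triangle writes exactly 3 data rows
  tri <- complete_graph(c("A", "B", "C"))
  write_network(tri, tsv)
  expect_length(readLines(tsv), 4L)  # header + 3
  # empty-edge graphs are refused
  expect_error(write_network(as_interactome(matrix(character(), 0, 2),
                                            nodes = c("A", "B")), tsv),
               class = "spanet_empty_error")
})

test_that("annotation loading maps aspects, fills sentinels, errors on bad codes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("X\tP\tGO:1", "X\tF\tGO:2", "X\tC\tGO:3", "Y\tP\tGO:9"), path)
  ann <- read_annotations(path, proteins = c("X", "Y", "Z"))
  expect_equal(ann$terms$X$process, "GO:1")
  expect_equal(ann$terms$X$`function`, "GO:2")
  expect_equal(ann$terms$X$component, "GO:3")
  sent <- go_unknown_terms()
  # Y has only a process row: the other aspects fall back to sentinels
  expect_equal(ann$terms$Y$`function`, unname(sent[["function"]]))
  expect_equal(ann$terms$Y$component, unname(sent[["component"]]))
  # Z is absent from the file entirely
  expect_equal(ann$terms$Z$process, unname(sent[["process"]]))
  writeLines(c("X\tP\tGO:1", "X\tQ\tGO:2"), path)
  expect_error(read_annotations(path), "row 2",
               class = "spanet_format_error")
})

test_that("annotation table round trip preserves generated truth", {
  g <- generate_interactome(60, 2, seed = 3)
  core <- igraph::V(g)$name[1:3]
  gen <- generate_annotations(g, core, seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(gen$annotations, path)
  back <- read_annotations(path, proteins = igraph::V(g)$name)
  for (p in igraph::V(g)$name) {
    for (a in c("process", "function", "component")) {
      expect_setequal(back$terms[[p]][[a]], gen$annotations$terms[[p]][[a]])
    }
  }
})

test_that("induced subnetworks match a brute-force edge filter", {
  tri <- complete_graph(c("A", "B", "C"))
  sub <- induce_network(tri, c("A", "B"))
  expect_equal(igraph::ecount(sub), 1L)
  expect_identical(spanet:::edge_keys(induce_network(tri, c("A", "B", "C"))),
                   spanet:::edge_keys(tri))
  expect_warning(induce_network(tri, c("A", "nope")), "ignored")
  for (seed in 1:5) {
    rg <- random_edge_matrix(50, 0.08, seed)
    g <- as_interactome(rg$edges, nodes = rg$nodes)
    set.seed(seed + 100)
    keep <- sample(rg$nodes, 25)
    sub <- induce_network(g, keep)
    want <- rg$edges[rg$edges[, 1L] %in% keep & rg$edges[, 2L] %in% keep, ,
                     drop = FALSE]
    want_keys <- sort(paste(pmin(want[, 1L], want[, 2L]),
                            pmax(want[, 1L], want[, 2L]), sep = "|"))
    expect_identical(spanet:::edge_keys(sub), want_keys)
    expect_setequal(igraph::V(sub)$name, keep)
  }
})
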