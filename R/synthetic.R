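#' Generate a heavy-tailed synthetic interactome
#'
#' Grows a connected simple graph by preferential attachment, emulating the
#' scale-free degree regime of curated physical interactomes.  Deterministic
#' for a fixed seed.
#'
#' @param n number of proteins (must be at least \code{attachment + 1}).
#' @param attachment number of edges each incoming protein attaches with;
#'   \code{attachment = 1} grows a tree.
#' @param seed integer RNG seed.
#' @return an interactome graph with protein identifiers \code{P0001}, ...
#' @export
generate_interactome <- function(n, attachment = 2, seed = 1) {
  if (attachment < 1L) {
    stop_spanet("`attachment` must be >= 1", "spanet_parameter_error")
  }
  if (n < attachment + 1L) {
    stop_spanet("`n` must be at least attachment + 1", "spanet_parameter_error")
  }
  g <- with_seed(seed, igraph::sample_pa(n, m = attachment, directed = FALSE))
  igraph::V(g)$name <- sprintf("P%04d", seq_len(n))
  validate_interactome(igraph::simplify(g))
}

#' Generate GO annotations with a planted admissible region
#'
#' Builds the ground truth for the selective-permissibility expansion: a
#' breadth-first growth from the core admits each newly reached neighbor
#' with probability \code{admit_prob}; the resulting admissible set is then
#' made exact by construction of the annotations.  Admissible proteins draw
#' terms only from the core-pooled vocabulary (with probability
#' \code{unknown_prob} an aspect is left to the root "unknown" sentinel);
#' every other protein receives a fresh out-of-vocabulary term violating the
#' configured permissibility mode in one randomly chosen aspect.  Running
#' [spa_expand()] on the fixture therefore returns exactly
#' \code{truth$admissible}.
#'
#' @param g interactome graph.
#' @param core character vector of core proteins (subset of the nodes).
#' @param vocab_sizes named integer vector: per-aspect core vocabulary sizes.
#' @param admit_prob probability a newly reached frontier neighbor is
#'   admissible; 1 floods the core's connected component, 0 restricts the
#'   admissible set to the core itself.
#' @param unknown_prob probability an admissible protein's aspect is the
#'   sentinel term.
#' @param mode permissibility mode the fixture is built for ("any" or "all").
#' @param seed integer RNG seed.
#' @return list with \code{annotations} (an [annotation_table()]) and
#'   \code{truth} (admissible set, seeds, parameters).
#' @export
generate_annotations <- function(g, core,
                                 vocab_sizes = c(process = 12, `function` = 8,
                                                 component = 6),
                                 admit_prob = 0.9, unknown_prob = 0.1,
                                 mode = c("any", "all"), seed = 1) {
  mode <- match.arg(mode)
  g <- validate_interactome(g)
  core <- unique(as.character(core))
  if (!all(core %in% igraph::V(g)$name)) {
    stop_spanet("`core` must be a subset of the interactome nodes",
                "spanet_parameter_error")
  }
  if (admit_prob < 0 || admit_prob > 1 || unknown_prob < 0 || unknown_prob > 1) {
    stop_spanet("probabilities must lie in [0, 1]", "spanet_parameter_error")
  }
  sent <- go_unknown_terms()
  nodes <- igraph::V(g)$name
  res <- with_seed(seed, {
    vocab <- list(
      process = sprintf("GO:1%06d", seq_len(vocab_sizes[["process"]])),
      `function` = sprintf("GO:2%06d", seq_len(vocab_sizes[["function"]])),
      component = sprintf("GO:3%06d", seq_len(vocab_sizes[["component"]]))
    )
    terms <- list()
    # Core proteins define the collection: 1-3 vocabulary terms per aspect.
    for (p in core) {
      terms[[p]] <- lapply(vocab, function(v) {
        sample(v, sample(1:min(3L, length(v)), 1L))
      })
    }
    pooled <- lapply(aspect_names(), function(a) {
      unique(unlist(lapply(core, function(p) terms[[p]][[a]])))
    })
    names(pooled) <- aspect_names()
    # Breadth-first admission from the core; each node is decided exactly
    # once, so the admissible set is closed under the permissibility check.
    admissible <- core
    decided <- structure(rep(TRUE, length(core)), names = core)
    queue <- core
    while (length(queue) > 0L) {
      u <- queue[[1L]]; queue <- queue[-1L]
      nb <- sort(nodes[unlist(igraph::adjacent_vertices(g, u))])
      for (v in nb) {
        if (!isTRUE(decided[v])) {
          decided[v] <- TRUE
          if (stats::runif(1) < admit_prob) {
            admissible <- c(admissible, v)
            queue <- c(queue, v)
          }
        }
      }
    }
    fresh_counter <- 0L
    fresh_term <- function() {
      fresh_counter <<- fresh_counter + 1L
      sprintf("GO:9%06d", fresh_counter)
    }
    draw_pooled <- function(a) {
      if (stats::runif(1) < unknown_prob) {
        unname(sent[[a]])
      } else {
        sample(pooled[[a]], sample(1:min(2L, length(pooled[[a]])), 1L))
      }
    }
    for (p in setdiff(nodes, core)) {
      if (p %in% admissible) {
        tt <- lapply(aspect_names(), draw_pooled)
        names(tt) <- aspect_names()
      } else {
        bad <- sample(aspect_names(), 1L)
        tt <- lapply(aspect_names(), draw_pooled)
        names(tt) <- aspect_names()
        # violate the configured criterion in exactly one aspect
        tt[[bad]] <- if (mode == "any") fresh_term() else
          c(sample(pooled[[bad]], 1L), fresh_term())
      }
      terms[[p]] <- tt
    }
    list(terms = terms, admissible = sort(admissible))
  })
  truth <- list(
    admissible = res$admissible,
    backbones = list(),
    seeds = seed,
    params = list(mode = mode, admit_prob = admit_prob,
                  unknown_prob = unknown_prob,
                  vocab_sizes = as.list(vocab_sizes))
  )
  list(annotations = annotation_table(res$terms), truth = truth)
}

#' Plant a high-participation path backbone between two proteins
#'
#' Adds a chain \code{input - B2 - ... - B(L-1) - output} of fresh backbone
#' proteins plus \code{corridor_width} parallel decoy proteins per
#' intermediate position, each decoy wired to the backbone proteins at the
#' two adjacent positions.  No two decoys are ever adjacent, so within the
#' corridor the backbone protein's positional participation strictly exceeds
#' every decoy's, and each backbone protein appears only at its own
#' position.  The planted truth records the backbone and decoy proteins per
#' position.
#'
#' @param g interactome graph.
#' @param input,output distinct proteins of \code{g}.
#' @param L node length of the planted paths (at least 3).
#' @param corridor_width decoys per intermediate position (0 plants a single
#'   chain).
#' @param prefix identifier prefix for the new proteins.
#' @return list with \code{graph} (augmented interactome) and \code{truth}
#'   (\code{backbone}, \code{decoys}: position-indexed protein sets).
#' @export
plant_backbone <- function(g, input, output, L = 6, corridor_width = 2,
                           prefix = "BB") {
  g <- validate_interactome(g)
  if (L < 3L) stop_spanet("`L` must be at least 3", "spanet_parameter_error")
  if (identical(input, output)) {
    stop_spanet("`input` and `output` must differ", "spanet_parameter_error")
  }
  nodes <- igraph::V(g)$name
  if (!all(c(input, output) %in% nodes)) {
    stop_spanet("`input` and `output` must be nodes of the graph",
                "spanet_parameter_error")
  }
  pos <- 2:(L - 1L)
  backbone <- stats::setNames(sprintf("%s%02d", prefix, pos), pos)
  decoys <- lapply(pos, function(i) {
    if (corridor_width == 0L) character() else
      sprintf("%sD%02d_%02d", prefix, i, seq_len(corridor_width))
  })
  names(decoys) <- pos
  newv <- c(unname(backbone), unlist(decoys, use.names = FALSE))
  if (any(newv %in% nodes)) {
    stop_spanet("backbone prefix collides with existing protein identifiers",
                "spanet_parameter_error")
  }
  g2 <- igraph::add_vertices(g, length(newv), name = newv)
  at_pos <- function(i) {            # backbone occupant of position i
    if (i == 1L) input else if (i == L) output else backbone[[as.character(i)]]
  }
  edges <- character()
  for (i in seq_len(L - 1L)) edges <- c(edges, at_pos(i), at_pos(i + 1L))
  for (i in pos) {
    for (d in decoys[[as.character(i)]]) {
      edges <- c(edges, d, at_pos(i - 1L), d, at_pos(i + 1L))
    }
  }
  g2 <- igraph::simplify(igraph::add_edges(g2, edges))
  truth <- list(
    input = input, output = output, L = L,
    corridor_width = corridor_width,
    backbone = as.list(backbone),
    decoys = decoys
  )
  list(graph = validate_interactome(g2), truth = truth)
}

#' Write a synthetic fixture to a directory
#'
#' Writes the interactome (BioGRID-style TSV), the annotation table
#' (three-column TSV), the core list, optional input/output pairs and the
#' ground truth (JSON, schema-versioned).  [read_fixture()] restores all
#' components losslessly.
#'
#' @param g interactome graph.
#' @param annotations an [annotation_table()].
#' @param truth ground-truth list (admissible set, backbones, seeds, params).
#' @param dir output directory (created if needed).
#' @param core optional core protein list.
#' @param pairs optional two-column data frame of input/output pairs.
#' @export
write_fixture <- function(g, annotations, truth, dir, core = NULL,
                          pairs = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_spanet(paste0("cannot create directory: ", dir),
                         "spanet_io_error")
  }
  write_network(g, file.path(dir, "interactions.tsv"), format = "tsv")
  write_annotations(annotations, file.path(dir, "annotations.tsv"))
  truth$schema <- "spanet-fixture/1"
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(core)) {
    writeLines(as.character(core), file.path(dir, "core.txt"))
  }
  if (!is.null(pairs)) {
    utils::write.table(pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read back a fixture directory written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return list with \code{graph}, \code{annotations}, \code{truth}, and
#'   (when present) \code{core} and \code{pairs}.
#' @export
read_fixture <- function(dir) {
  g <- read_interactions(file.path(dir, "interactions.tsv"), quiet = TRUE)
  ann <- read_annotations(file.path(dir, "annotations.tsv"),
                          proteins = igraph::V(g)$name)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  out <- list(graph = g, annotations = ann, truth = truth)
  core_path <- file.path(dir, "core.txt")
  if (file.exists(core_path)) out$core <- readLines(core_path)
  pairs_path <- file.path(dir, "pairs.tsv")
  if (file.exists(pairs_path)) {
    out$pairs <- utils::read.delim(pairs_path, header = FALSE,
                                   colClasses = "character")
  }
  out
}
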