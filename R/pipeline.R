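#' Build a pipeline configuration
#'
#' Collects file paths, stage parameters and seeds for [run_pipeline()].
#' All randomness is funneled through the explicit \code{seed}; there is no
#' wall-clock seeding anywhere.  A configuration can also be read from a
#' YAML file with [read_pipeline_config()].
#'
#' @param interactions,annotations,core,pairs input file paths (interaction
#'   TSV, annotation TSV, one core protein per line, two-column input/output
#'   pairs TSV).
#' @param out_dir output directory.
#' @param mode permissibility mode for the expansion.
#' @param alpha,n_random,swaps_per_edge tuning parameters.
#' @param L,cap path enumeration parameters.
#' @param fold fold-change direction for the key-protein decomposition.
#' @param seed master seed.
#' @param protect_endpoints protect the path input/output proteins from
#'   removal during tuning so that every configured branch can be analyzed.
#' @param physical_only restrict loading to physical interactions.
#' @return a named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(interactions, annotations, core, pairs, out_dir,
                            mode = "any", alpha = 0.001, n_random = 100,
                            swaps_per_edge = 10, L = 6, cap = 2e6,
                            fold = "decay", seed = 1,
                            protect_endpoints = TRUE, physical_only = TRUE) {
  cfg <- list(interactions = interactions, annotations = annotations,
              core = core, pairs = pairs, out_dir = out_dir, mode = mode,
              alpha = alpha, n_random = n_random,
              swaps_per_edge = swaps_per_edge, L = L, cap = cap, fold = fold,
              seed = seed, protect_endpoints = protect_endpoints,
              physical_only = physical_only)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full reconstruction / tuning / dissection pipeline
#'
#' Executes the stages in order -- selective-permissibility expansion,
#' betweenness-centrality tuning, topological characterization, linear path
#' enumeration per configured input/output pair, step-specific key-protein
#' extraction and heart-network assembly -- writing each stage's outputs
#' under \code{out_dir} and a machine-readable JSON run manifest recording
#' parameters, seeds and output-file digests.  Pairs with no path of the
#' configured length in the tuned network are skipped with a warning and
#' recorded in the manifest.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  written <- character()
  emit <- function(path) { written <<- c(written, path); path }

  # --- load inputs -------------------------------------------------------
  g <- read_interactions(config$interactions,
                         physical_only = config$physical_only, quiet = TRUE)
  core <- readLines(config$core)
  core <- core[nzchar(core)]
  ann <- read_annotations(config$annotations, proteins = igraph::V(g)$name)
  pairs <- utils::read.delim(config$pairs, header = FALSE,
                             colClasses = "character")
  if (ncol(pairs) < 2L) {
    stop_spanet("pairs file must have two tab-separated columns",
                "spanet_format_error")
  }

  # --- stage 1: reconstruction ------------------------------------------
  rec <- spa_expand(core, g, ann, mode = config$mode)
  emit(write_network(rec$network, file.path(out, "network.tsv")))
  emit(write_network(rec$network, file.path(out, "network.graphml"),
                     format = "graphml"))
  emit(write_tsv(rec$log, file.path(out, "expansion_log.tsv")))

  # --- stage 2: tuning ---------------------------------------------------
  protect <- if (isTRUE(config$protect_endpoints)) {
    unique(c(pairs[[1L]], pairs[[2L]]))
  } else character()
  tuned <- tune_network(rec$network, alpha = config$alpha,
                        n_random = config$n_random,
                        swaps_per_edge = config$swaps_per_edge,
                        seed = config$seed, protect = protect)
  emit(write_network(tuned$network, file.path(out, "tuned_network.tsv")))
  emit(write_tsv(tuned$report, file.path(out, "tuning_report.tsv")))

  # --- stage 3: topology -------------------------------------------------
  topo <- list(reconstructed = topology_flat(topology_summary(rec$network)),
               tuned = topology_flat(topology_summary(tuned$network)))
  jsonlite::write_json(topo, emit(file.path(out, "topology.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  # --- stage 4: linear paths --------------------------------------------
  tuned_nodes <- igraph::V(tuned$network)$name
  spectra <- list()
  skipped <- list()
  for (r in seq_len(nrow(pairs))) {
    inp <- pairs[r, 1L]; outp <- pairs[r, 2L]
    if (!all(c(inp, outp) %in% tuned_nodes)) {
      warning(sprintf("pair %s -> %s: endpoint absent from tuned network",
                      inp, outp), call. = FALSE)
      skipped[[length(skipped) + 1L]] <- c(inp, outp, "endpoint absent")
      next
    }
    sp <- enumerate_paths(tuned$network, inp, outp, L = config$L,
                          cap = config$cap)
    if (nrow(sp$paths) == 0L) {
      warning(sprintf("pair %s -> %s: no path of length %d",
                      inp, outp, config$L), call. = FALSE)
      skipped[[length(skipped) + 1L]] <- c(inp, outp, "no paths")
      next
    }
    spectra[[length(spectra) + 1L]] <- sp
    utils::write.table(sp$paths,
                       emit(file.path(out, sprintf("paths_%s_%s.tsv",
                                                   inp, outp))),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  if (length(spectra) == 0L) {
    stop_spanet("no analyzable input/output pair survived tuning",
                "spanet_pipeline_error")
  }
  metrics <- do.call(rbind, lapply(
    unique(vapply(spectra, function(s) s$output, character(1))),
    function(o) {
      spectrum_metrics(Filter(function(s) s$output == o, spectra),
                       core = core, network = tuned$network)
    }))
  emit(write_tsv(metrics, file.path(out, "path_metrics.tsv")))

  # --- stage 5: key proteins & heart network ----------------------------
  branches <- lapply(spectra, stepwise_keys, fold = config$fold)
  key_rows <- do.call(rbind, lapply(branches, function(b) {
    do.call(rbind, lapply(seq_along(b$keys), function(s) {
      data.frame(input = b$input, output = b$output, step = s,
                 position = s + 1L,
                 protein = b$keys[[s]],
                 subset_size = b$subset_sizes[s])
    }))
  }))
  emit(write_tsv(key_rows, file.path(out, "key_proteins.tsv")))
  heart <- assemble_heart(branches,
                          inputs = unique(pairs[[1L]]),
                          outputs = unique(pairs[[2L]]),
                          g = tuned$network, spectra = spectra)
  emit(write_network(heart$network, file.path(out, "heart_network.tsv")))
  emit(write_network(heart$network, file.path(out, "heart_network.graphml"),
                     format = "graphml"))
  emit(write_tsv(heart$coverage, file.path(out, "heart_coverage.tsv")))

  # --- manifest ----------------------------------------------------------
  digests <- as.list(tools::md5sum(sort(unique(written))))
  names(digests) <- basename(names(digests))
  manifest <- list(
    package_version = as.character(utils::packageVersion("spanet")),
    config = unclass(config),
    stages = list(
      reconstruction = list(nodes = igraph::vcount(rec$network),
                            edges = igraph::ecount(rec$network),
                            iterations = nrow(rec$log)),
      tuning = list(nodes = igraph::vcount(tuned$network),
                    edges = igraph::ecount(tuned$network),
                    pct_nodes_removed = tuned$summary$pct_nodes_removed,
                    pct_edges_removed = tuned$summary$pct_edges_removed),
      paths = list(n_branches = length(spectra),
                   skipped = skipped),
      heart = list(nodes = length(heart$members),
                   edges = igraph::ecount(heart$network))
    ),
    output_digests = digests
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# flatten a topology_summary into plain scalars for JSON
topology_flat <- function(ts) {
  list(nodes = ts$nodes, edges = ts$edges, mean_degree = ts$mean_degree,
       cpl = ts$cpl, diameter = ts$diameter,
       mean_clustering = ts$mean_clustering,
       gamma = if (!is.null(ts$degree_fit)) ts$degree_fit$exponent else NULL,
       gamma_r2 = if (!is.null(ts$degree_fit)) ts$degree_fit$r2 else NULL,
       w = if (!is.null(ts$clustering_fit)) ts$clustering_fit$exponent
           else NULL,
       w_r2 = if (!is.null(ts$clustering_fit)) ts$clustering_fit$r2
              else NULL)
}

#' Simulate a complete annotated fixture ready for [run_pipeline()]
#'
#' Generates a preferential-attachment interactome, selects core proteins,
#' plants a path backbone between two of them, generates annotations with a
#' planted admissible region, and writes everything (interactions,
#' annotations, core list, pairs, ground truth) into \code{dir}.
#'
#' @param dir output directory.
#' @param n,attachment interactome size parameters.
#' @param n_core number of core proteins (picked among well-connected
#'   nodes so the admissible region has room to grow).
#' @param admit_prob,unknown_prob,mode annotation-generator parameters.
#' @param L,corridor_width backbone parameters.
#' @param seed master seed.
#' @return the fixture directory, invisibly; the ground truth is in
#'   \code{truth.json}.
#' @export
simulate_fixture <- function(dir, n = 300, attachment = 2, n_core = 6,
                             admit_prob = 0.9, unknown_prob = 0.1,
                             mode = "any", L = 6, corridor_width = 2,
                             seed = 1) {
  seeds <- derive_seeds(seed, 3L)
  g <- generate_interactome(n, attachment = attachment, seed = seeds[1L])
  deg <- igraph::degree(g)
  eligible <- names(sort(deg, decreasing = TRUE))[seq_len(min(50L, n))]
  core <- with_seed(seeds[2L], sort(sample(eligible, n_core)))
  input <- core[1L]; output <- core[2L]
  planted <- plant_backbone(g, input, output, L = L,
                            corridor_width = corridor_width)
  gen <- generate_annotations(planted$graph, core,
                              admit_prob = admit_prob,
                              unknown_prob = unknown_prob,
                              mode = mode, seed = seeds[3L])
  truth <- gen$truth
  truth$backbones <- list(list(input = input, output = output,
                               L = L, corridor_width = corridor_width,
                               backbone = planted$truth$backbone,
                               decoys = planted$truth$decoys))
  truth$seeds <- c(seed, seeds)
  pairs <- data.frame(input = c(input, core[3L]),
                      output = c(output, output))
  write_fixture(planted$graph, gen$annotations, truth, dir,
                core = core, pairs = pairs)
  invisible(dir)
}
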