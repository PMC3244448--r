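#' Shortest-path betweenness centrality
#'
#' Unnormalized node betweenness: for each node, the sum over unordered
#' source-target pairs (endpoints excluded) of the fraction of shortest
#' paths passing through the node.  Disconnected graphs are handled; pairs
#' in different components contribute nothing.
#'
#' @param g interactome graph.
#' @return named numeric vector of betweenness values.
#' @export
node_betweenness <- function(g) {
  g <- validate_interactome(g)
  igraph::betweenness(g, directed = FALSE, normalized = FALSE)
}

#' Degree-preserving randomization by double-edge swaps
#'
#' Rewires the graph with the classic double-edge swap: two edges (a,b) and
#' (c,d) are replaced by (a,d) and (c,b), rejecting any swap that would
#' create a self-loop or a multi-edge.  Exactly
#' \code{swaps_per_edge * ecount(g)} successful swaps are performed (or as
#' many as a bounded number of attempts permits).  Every node's degree is
#' identical to the input graph's, which is the defining invariant of the
#' null model.
#'
#' @param g interactome graph with at least 2 edges.
#' @param swaps_per_edge target number of successful swaps per edge
#'   (default 10, a standard mixing heuristic).
#' @param seed integer RNG seed (NULL uses the current RNG state).
#' @param max_tries_factor bound on attempted swaps, as a multiple of the
#'   target; if no valid swap is ever found (e.g. a triangle) the original
#'   graph is returned with a warning.
#' @return a rewired interactome with the same vertex set and degrees.
#' @export
rewire_degree_preserving <- function(g, swaps_per_edge = 10, seed = NULL,
                                     max_tries_factor = 100) {
  g <- validate_interactome(g)
  m <- igraph::ecount(g)
  if (m < 2L) {
    stop_spanet("graph must have at least 2 edges to rewire",
                "spanet_parameter_error")
  }
  run <- function() {
    el <- igraph::as_edgelist(g, names = FALSE)
    eset <- new.env(hash = TRUE, parent = emptyenv())
    ekey <- function(i, j) paste0(min(i, j), "|", max(i, j))
    for (r in seq_len(m)) assign(ekey(el[r, 1L], el[r, 2L]), TRUE, envir = eset)
    target <- as.integer(swaps_per_edge * m)
    max_tries <- max(1000L, as.integer(max_tries_factor) * target)
    successes <- 0L
    tries <- 0L
    while (successes < target && tries < max_tries) {
      tries <- tries + 1L
      idx <- sample.int(m, 2L)
      e1 <- el[idx[1L], ]; e2 <- el[idx[2L], ]
      if (stats::runif(1) < 0.5) e2 <- rev(e2)  # random orientation
      a <- e1[1L]; b <- e1[2L]; c_ <- e2[1L]; d <- e2[2L]
      # proposed replacement: (a,d) and (c,b)
      if (a == d || c_ == b) next
      k1 <- ekey(a, d); k2 <- ekey(c_, b)
      if (exists(k1, envir = eset, inherits = FALSE) ||
          exists(k2, envir = eset, inherits = FALSE) || k1 == k2) next
      rm(list = c(ekey(a, b), ekey(c_, d)), envir = eset)
      assign(k1, TRUE, envir = eset)
      assign(k2, TRUE, envir = eset)
      el[idx[1L], ] <- c(a, d)
      el[idx[2L], ] <- c(c_, b)
      successes <- successes + 1L
    }
    list(el = el, successes = successes, target = target)
  }
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  if (res$successes == 0L) {
    warning("graph admits no valid degree-preserving swap; returned unchanged",
            call. = FALSE)
    return(g)
  }
  if (res$successes < res$target) {
    warning(sprintf(
      "only %d of %d target swaps succeeded within the attempt bound",
      res$successes, res$target), call. = FALSE)
  }
  g2 <- igraph::add_edges(igraph::delete_edges(g, igraph::E(g)),
                          as.vector(t(res$el)))
  validate_interactome(g2)
}

#' Per-node betweenness significance test against a null sample
#'
#' Dependent two-tailed t-test for paired samples: the observed value is
#' paired against each of the null draws, which for a constant observation
#' reduces to a one-sample t-test on the differences
#' \eqn{d_i = bc_{obs} - bc_{null,i}} with \eqn{R - 1} degrees of freedom.
#' Degenerate cases: all differences zero gives p = 1 (the node behaves
#' identically in the random ensemble, so it is discarded); zero spread with
#' a nonzero mean difference gives p = 0 (kept).
#'
#' @param bc_obs observed betweenness value.
#' @param bc_null numeric vector of null betweenness values (length >= 2).
#' @param alpha significance level; the node is kept iff p < alpha.
#' @return list with \code{t}, \code{p} and logical \code{keep}.
#' @export
significance_test <- function(bc_obs, bc_null, alpha = 0.001) {
  if (length(bc_null) < 2L) {
    stop_spanet("at least 2 null samples are required",
                "spanet_parameter_error")
  }
  d <- bc_obs - bc_null
  R <- length(d)
  md <- mean(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (md == 0) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(md) * Inf; p <- 0
    }
  } else {
    t_stat <- md / (sd_d / sqrt(R))
    p <- 2 * stats::pt(-abs(t_stat), df = R - 1L)
  }
  list(t = t_stat, p = p, keep = p < alpha)
}

#' Skewness control chart for the randomized ensemble
#'
#' Each random network's betweenness distribution is summarized by its
#' sample skewness; the center line is the skewness of the reference
#' (original) network's betweenness distribution and the control limits are
#' CL plus/minus three standard deviations of the ensemble skewness values.
#' Networks outside the limits are flagged for regeneration.
#'
#' @param null_bc list (or matrix rows) of betweenness vectors, one per
#'   random network.
#' @param reference_bc betweenness vector of the original network.
#' @return list with \code{skewness}, \code{cl}, \code{sigma}, \code{ucl},
#'   \code{lcl} and logical \code{flagged}.
#' @export
control_chart <- function(null_bc, reference_bc) {
  if (is.matrix(null_bc)) {
    null_bc <- lapply(seq_len(nrow(null_bc)), function(i) null_bc[i, ])
  }
  sk <- vapply(null_bc, sample_skewness, numeric(1))
  cl <- sample_skewness(reference_bc)
  sigma <- stats::sd(sk)
  if (!is.finite(sigma) || sigma == 0) {
    flagged <- rep(FALSE, length(sk))
    ucl <- cl; lcl <- cl
  } else {
    ucl <- cl + 3 * sigma
    lcl <- cl - 3 * sigma
    flagged <- sk > ucl | sk < lcl
  }
  list(skewness = sk, cl = cl, sigma = sigma, ucl = ucl, lcl = lcl,
       flagged = flagged)
}

#' Tune a network by betweenness-centrality significance
#'
#' Generates \code{n_random} degree-preserving randomizations (quality
#' checked with the skewness control chart; flagged networks are regenerated
#' with fresh seeds), computes every node's betweenness in the original and
#' each null network, runs the per-node paired t-test, and discards
#' non-significant nodes together with all their incident edges.
#'
#' @param g interactome graph.
#' @param alpha per-node significance level (0.001 by default; 0.1, 0.01 and
#'   0.001 are the conventional choices to compare).
#' @param n_random size of the null ensemble (default 100).
#' @param swaps_per_edge double-edge swaps per edge for each randomization.
#' @param seed master RNG seed; all per-network seeds derive from it.
#' @param protect protein identifiers never removed regardless of p-value.
#' @param prune_isolates drop kept nodes left with no interactions.
#' @param use_control_chart run the skewness control chart (default TRUE).
#' @param max_regen bounded retries for flagged null networks.
#' @return list with \code{network} (tuned interactome), \code{report} (one
#'   row per node: observed BC, null mean/sd, t, p, keep) and \code{summary}
#'   (parameters, removal percentages, control-chart record).
#' @export
tune_network <- function(g, alpha = 0.001, n_random = 100, swaps_per_edge = 10,
                         seed = 1, protect = character(),
                         prune_isolates = FALSE, use_control_chart = TRUE,
                         max_regen = 10) {
  g <- validate_interactome(g)
  nodes <- igraph::V(g)$name
  bc_obs <- node_betweenness(g)
  seeds <- derive_seeds(seed, n_random + max_regen * n_random)
  seed_cursor <- n_random
  null_seeds <- seeds[seq_len(n_random)]
  gen_null <- function(s) {
    gn <- rewire_degree_preserving(g, swaps_per_edge = swaps_per_edge,
                                   seed = s)
    node_betweenness(gn)[nodes]
  }
  null_bc <- lapply(null_seeds, gen_null)
  chart <- NULL
  regen_rounds <- 0L
  if (use_control_chart) {
    repeat {
      chart <- control_chart(null_bc, bc_obs)
      if (!any(chart$flagged)) break
      regen_rounds <- regen_rounds + 1L
      if (regen_rounds > max_regen) {
        stop_spanet(sprintf(
          "control chart: %d null networks still flagged after %d regeneration rounds",
          sum(chart$flagged), max_regen), "spanet_tuning_error")
      }
      for (i in which(chart$flagged)) {
        seed_cursor <- seed_cursor + 1L
        null_seeds[i] <- seeds[seed_cursor]
        null_bc[[i]] <- gen_null(null_seeds[i])
      }
    }
  }
  null_mat <- do.call(rbind, null_bc)  # n_random x n_nodes
  report <- do.call(rbind, lapply(seq_along(nodes), function(j) {
    st <- significance_test(bc_obs[[j]], null_mat[, j], alpha = alpha)
    data.frame(protein = nodes[j],
               degree = unname(igraph::degree(g, nodes[j])),
               bc_obs = unname(bc_obs[[j]]),
               null_mean = mean(null_mat[, j]),
               null_sd = stats::sd(null_mat[, j]),
               t = st$t, p = st$p, keep = st$keep)
  }))
  rownames(report) <- NULL
  protected <- intersect(as.character(protect), nodes)
  kept <- union(report$protein[report$keep], protected)
  tuned <- induce_network(g, kept)
  if (prune_isolates) {
    tuned <- igraph::delete_vertices(tuned, igraph::degree(tuned) == 0)
  }
  pct_nodes_removed <- 100 * (1 - igraph::vcount(tuned) / igraph::vcount(g))
  pct_edges_removed <- 100 * (1 - igraph::ecount(tuned) / igraph::ecount(g))
  list(
    network = tuned,
    report = report,
    summary = list(alpha = alpha, n_random = n_random,
                   swaps_per_edge = swaps_per_edge, seed = seed,
                   null_seeds = null_seeds,
                   protected = protected,
                   regen_rounds = regen_rounds,
                   pct_nodes_removed = pct_nodes_removed,
                   pct_edges_removed = pct_edges_removed,
                   control_chart = chart)
  )
}
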