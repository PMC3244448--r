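#' Fit a power law by ordinary least squares on log-log scales
#'
#' Fits \eqn{y = c x^{-e}} by linear regression of \eqn{\log_{10} y} on
#' \eqn{\log_{10} x}, the conventional fitting style for raw degree and
#' clustering spectra of interaction networks.  The returned exponent is the
#' negated slope, so a decaying spectrum yields a positive exponent.
#'
#' @param x,y positive numeric vectors (at least 3 distinct abscissae).
#' @return object of class \code{power_law_fit}: list with \code{exponent},
#'   \code{intercept}, \code{r2} and \code{support}.
#' @export
fit_power_law <- function(x, y) {
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 3L) {
    stop_spanet("power-law fit requires at least 3 distinct positive abscissae",
                "spanet_fit_error")
  }
  fit <- stats::lm(log10(y) ~ log10(x))
  # exact power laws are legitimate inputs; silence summary.lm's
  # "essentially perfect fit" note
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(exponent = -unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r2 = r2,
         support = sort(unique(x))),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> exponent = %.3f, R^2 = %.3f (%d abscissae)\n",
              x$exponent, x$r2, length(x$support)))
  invisible(x)
}

#' Power-law fit of the degree distribution
#'
#' Computes the raw (non-binned, non-cumulative) empirical degree
#' distribution P(k) over observed degrees k >= 1 and fits it on log-log
#' scales; the exponent is the scale-free exponent gamma.
#'
#' @param g interactome graph.
#' @return a [fit_power_law()] object.
#' @export
degree_fit <- function(g) {
  g <- validate_interactome(g)
  deg <- igraph::degree(g)
  tab <- table(deg[deg >= 1])
  k <- as.numeric(names(tab))
  pk <- as.numeric(tab) / igraph::vcount(g)
  fit_power_law(k, pk)
}

#' Power-law fit of the clustering spectrum C(k)
#'
#' C(k) is the mean local clustering coefficient over nodes of degree k; a
#' power-law decay of C(k) is the signature of hierarchical (modular)
#' organization.  Degrees with zero mean clustering carry no information on
#' log scales and are dropped; at least 3 positive C(k) values are required.
#'
#' @param g interactome graph.
#' @return a [fit_power_law()] object.
#' @export
clustering_spectrum_fit <- function(g) {
  g <- validate_interactome(g)
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  use <- deg >= 2
  if (!any(use)) {
    stop_spanet("no nodes of degree >= 2: clustering spectrum undefined",
                "spanet_fit_error")
  }
  ck <- tapply(cc[use], deg[use], mean)
  k <- as.numeric(names(ck))
  ck <- as.numeric(ck)
  pos <- ck > 0
  if (sum(pos) < 3L) {
    stop_spanet("fewer than 3 degrees with positive mean clustering",
                "spanet_fit_error")
  }
  fit_power_law(k[pos], ck[pos])
}

#' Topological summary of an interactome
#'
#' Node and edge counts, average degree, critical path length (mean shortest
#' path over connected pairs, computed within components), diameter of the
#' largest component, and the average local clustering coefficient (nodes of
#' degree < 2 contribute zero).  The power-law fits are included when they
#' are defined and NULL otherwise.
#'
#' @param g interactome graph.
#' @return list of class \code{topology_summary}.
#' @export
topology_summary <- function(g) {
  g <- validate_interactome(g)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  comps <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comps$membership == which.max(comps$csize)))
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  res <- list(
    nodes = n,
    edges = m,
    mean_degree = 2 * m / n,
    cpl = igraph::mean_distance(g, directed = FALSE, unconnected = TRUE),
    diameter = igraph::diameter(giant, directed = FALSE, unconnected = FALSE),
    mean_clustering = mean(cc),
    n_components = comps$no,
    degree_fit = tryCatch(degree_fit(g), error = function(e) NULL),
    clustering_fit = tryCatch(clustering_spectrum_fit(g),
                              error = function(e) NULL)
  )
  class(res) <- "topology_summary"
  res
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(
    "<topology_summary> %d nodes, %d edges, <k> = %.2f, CPL = %.2f, d = %d, <CC> = %.3f\n",
    x$nodes, x$edges, x$mean_degree, x$cpl, x$diameter, x$mean_clustering))
  if (!is.null(x$degree_fit)) {
    cat(sprintf("  P(k) ~ k^-%.2f (R^2 = %.2f)\n",
                x$degree_fit$exponent, x$degree_fit$r2))
  }
  if (!is.null(x$clustering_fit)) {
    cat(sprintf("  C(k) ~ k^-%.2f (R^2 = %.2f)\n",
                x$clustering_fit$exponent, x$clustering_fit$r2))
  }
  invisible(x)
}

#' Top-degree hub proteins
#'
#' The \code{top} most-connected proteins, ties broken by identifier
#' ascending for deterministic output.
#'
#' @param g interactome graph.
#' @param top number of hubs to return (clipped to the node count with a
#'   warning).
#' @return data frame with columns \code{protein} and \code{degree}.
#' @export
hubs <- function(g, top = 20) {
  g <- validate_interactome(g)
  if (top > igraph::vcount(g)) {
    warning("`top` exceeds the node count; returning all nodes",
            call. = FALSE)
    top <- igraph::vcount(g)
  }
  deg <- igraph::degree(g)
  ord <- order(-deg, names(deg))
  data.frame(protein = names(deg)[ord][seq_len(top)],
             degree = unname(deg[ord][seq_len(top)]),
             row.names = NULL)
}

#' Connected-component impact of deleting one protein
#'
#' Component count of the graph minus the protein (isolated survivors count
#' as components) and the fold change relative to the intact graph, the
#' standard deletion-robustness measure for hubs.
#'
#' @param g interactome graph.
#' @param v protein identifier to delete.
#' @return list with \code{components_before}, \code{components_after} and
#'   \code{fold_change}.
#' @export
components_after_deletion <- function(g, v) {
  g <- validate_interactome(g)
  if (!v %in% igraph::V(g)$name) {
    stop_spanet(paste0("protein not in the network: ", v),
                "spanet_parameter_error")
  }
  before <- igraph::components(g)$no
  after <- igraph::components(igraph::delete_vertices(g, v))$no
  list(components_before = before, components_after = after,
       fold_change = after / before)
}
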