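#' Enumerate all linear paths of a fixed node length
#'
#' Exact, complete, duplicate-free enumeration of the simple paths with
#' exactly \code{L} nodes (\code{L - 1} edges) from \code{input} to
#' \code{output}, by depth-bounded depth-first search with visited-set
#' pruning and a distance-to-target bound (a branch is abandoned as soon as
#' the output is unreachable in the remaining steps).  Paths are returned in
#' lexicographic order of their member identifiers.
#'
#' @param g interactome graph.
#' @param input,output distinct proteins of \code{g}.
#' @param L node length of the paths (at least 3); the default 6 gives four
#'   intermediate positions, i.e. five signaling steps.
#' @param cap maximum number of paths before an explosion error (condition
#'   class \code{spanet_explosion_error}, carrying the partial count) is
#'   raised.
#' @return object of class \code{path_spectrum}: list with \code{input},
#'   \code{output}, \code{L} and \code{paths}, a character matrix with one
#'   row per path and \code{L} columns.
#' @export
enumerate_paths <- function(g, input, output, L = 6, cap = 2e6) {
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
  n <- length(nodes)
  # adjacency as integer lists, neighbors sorted by protein identifier so
  # that depth-first emission is lexicographic
  adj <- lapply(igraph::adjacent_vertices(g, seq_len(n)), function(vs) {
    ix <- as.integer(vs)
    ix[order(nodes[ix])]
  })
  src <- match(input, nodes)
  dst <- match(output, nodes)
  dist_to_out <- suppressWarnings(
    as.integer(igraph::distances(g, v = dst, mode = "all"))
  )
  dist_to_out[is.na(dist_to_out)] <- .Machine$integer.max
  found <- vector("list", 1024L)
  n_found <- 0L
  visited <- logical(n)
  path <- integer(L)
  dfs <- function(v, depth) {
    path[depth] <<- v
    if (depth == L) {
      if (v == dst) {
        n_found <<- n_found + 1L
        if (n_found > cap) {
          stop_spanet(sprintf(
            "path explosion: more than %d paths (partial count %d)",
            as.integer(cap), n_found - 1L),
            "spanet_explosion_error", partial_count = n_found - 1L)
        }
        if (n_found > length(found)) {
          length(found) <<- 2L * length(found)
        }
        found[[n_found]] <<- path
      }
      return(invisible())
    }
    remaining <- L - depth
    visited[v] <<- TRUE
    for (w in adj[[v]]) {
      if (visited[w]) next
      if (w == dst && remaining > 1L) next  # output only at the last position
      if (dist_to_out[w] > remaining - 1L) next
      dfs(w, depth + 1L)
    }
    visited[v] <<- FALSE
    invisible()
  }
  visited[dst] <- FALSE
  dfs(src, 1L)
  paths <- if (n_found == 0L) {
    matrix(character(), nrow = 0L, ncol = L)
  } else {
    matrix(nodes[unlist(found[seq_len(n_found)])], ncol = L, byrow = TRUE)
  }
  structure(list(input = input, output = output, L = L, paths = paths),
            class = "path_spectrum")
}

#' @export
print.path_spectrum <- function(x, ...) {
  cat(sprintf("<path_spectrum> %s -> %s, L = %d: %d paths\n",
              x$input, x$output, x$L, nrow(x$paths)))
  invisible(x)
}

spectrum_union <- function(spectrum) {
  sort(unique(as.vector(spectrum$paths)))
}

#' Participation percentages of proteins in a path spectrum
#'
#' Global participation is the percentage of paths containing the protein
#' anywhere; positional participation is the percentage of paths with the
#' protein at exactly the given position (1-based node position along the
#' path).  Positional percentages at one position sum to 100.
#'
#' @param spectrum a nonempty [enumerate_paths()] spectrum.
#' @param position \code{"global"} or an integer position in \code{1:L}.
#' @return named numeric vector of percentages.
#' @export
participation <- function(spectrum, position = "global") {
  stopifnot(inherits(spectrum, "path_spectrum"))
  np <- nrow(spectrum$paths)
  if (np == 0L) {
    stop_spanet("participation is undefined for an empty spectrum",
                "spanet_parameter_error")
  }
  if (identical(position, "global")) {
    counts <- table(unlist(apply(spectrum$paths, 1L, unique,
                                 simplify = FALSE)))
    out <- 100 * as.numeric(counts) / np
    names(out) <- names(counts)
  } else {
    pos <- as.integer(position)
    if (is.na(pos) || pos < 1L || pos > spectrum$L) {
      stop_spanet("`position` must be 'global' or a position in 1..L",
                  "spanet_parameter_error")
    }
    counts <- table(spectrum$paths[, pos])
    out <- 100 * as.numeric(counts) / np
    names(out) <- names(counts)
  }
  out[order(names(out))]
}

#' Quantitative metrics of linear path spectra sharing one output
#'
#' For each input's spectrum: path count, protein count (the size of the
#' union of path members, endpoints included), unique proteins (members of
#' exactly one input's union among the provided spectra), core protein
#' coverage (CPC, percent of the network's core proteins present in the
#' union) and overall protein coverage (OPC, percent of the network's
#' proteins present in the union).
#'
#' @param spectra list of [enumerate_paths()] spectra with a common output.
#' @param core character vector of core proteins; the CPC denominator is the
#'   core proteins present in \code{network}.
#' @param network the interactome the spectra were enumerated in (OPC
#'   denominator).
#' @return data frame with one row per input.
#' @export
spectrum_metrics <- function(spectra, core, network) {
  stopifnot(length(spectra) > 0L)
  outs <- unique(vapply(spectra, function(s) s$output, character(1)))
  if (length(outs) != 1L) {
    stop_spanet("all spectra must share the same output protein",
                "spanet_parameter_error")
  }
  network <- validate_interactome(network)
  core_in_net <- intersect(as.character(core), igraph::V(network)$name)
  unions <- lapply(spectra, spectrum_union)
  tallies <- table(unlist(unions))
  res <- lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    u <- unions[[i]]
    if (nrow(s$paths) == 0L) {
      warning(sprintf("empty spectrum for %s -> %s", s$input, s$output),
              call. = FALSE)
      return(data.frame(input = s$input, output = s$output, n_paths = 0L,
                        n_proteins = 0L, n_unique = 0L, cpc = 0, opc = 0))
    }
    data.frame(
      input = s$input,
      output = s$output,
      n_paths = nrow(s$paths),
      n_proteins = length(u),
      n_unique = sum(tallies[u] == 1L),
      cpc = 100 * length(intersect(u, core_in_net)) /
        max(1L, length(core_in_net)),
      opc = 100 * length(u) / igraph::vcount(network)
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
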