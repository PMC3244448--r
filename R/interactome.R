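#' Interactome graphs
#'
#' An interactome is represented as an undirected, simple \pkg{igraph} graph
#' whose vertices carry protein identifiers in the \code{name} attribute.
#' Identifiers are nonempty, case-preserved strings; self-interactions and
#' duplicate interactions are never retained.
#'
#' @param edges a two-column character matrix or data frame of interacting
#'   protein pairs, or an \pkg{igraph} graph to be coerced.
#' @param nodes optional character vector of additional (possibly isolated)
#'   protein identifiers to include as vertices.
#' @return an undirected simple \code{igraph} graph.
#' @export
as_interactome <- function(edges, nodes = NULL) {
  if (igraph::is_igraph(edges)) {
    g <- edges
    if (is.null(igraph::V(g)$name)) {
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    }
    g <- igraph::as_undirected(g, mode = "collapse")
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
    return(validate_interactome(g))
  }
  el <- as.matrix(edges)
  if (ncol(el) < 2L) stop("`edges` must have two columns", call. = FALSE)
  el <- matrix(as.character(el[, 1:2]), ncol = 2L)
  keep <- el[, 1L] != el[, 2L]
  el <- el[keep, , drop = FALSE]
  verts <- unique(c(el[, 1L], el[, 2L], as.character(nodes)))
  if (any(!nzchar(verts)) || anyNA(verts)) {
    stop("protein identifiers must be nonempty strings", call. = FALSE)
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(verts), name = verts)
  if (nrow(el) > 0L) g <- igraph::add_edges(g, t(el))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  validate_interactome(g)
}

validate_interactome <- function(g) {
  stopifnot(igraph::is_igraph(g))
  nm <- igraph::V(g)$name
  if (is.null(nm) || anyNA(nm) || any(!nzchar(nm)) || anyDuplicated(nm)) {
    stop("interactome vertices must carry unique nonempty names",
         call. = FALSE)
  }
  if (igraph::any_loop(g) || igraph::any_multiple(g)) {
    stop("interactome must be a simple graph", call. = FALSE)
  }
  g
}

#' Read a protein-protein interaction file
#'
#' Accepts either a BioGRID TAB-style tab-delimited file (the columns used
#' are \sQuote{Official Symbol Interactor A}, \sQuote{Official Symbol
#' Interactor B} and \sQuote{Experimental System Type}) or a bare two-column
#' edge list without a header.  The dialect is detected by header sniffing.
#' Self-interactions are dropped and duplicate rows collapsed; a load summary
#' (rows read / dropped by reason) is attached as the \code{"load_summary"}
#' attribute and reported via \code{message()}.
#'
#' @param path path to a tab-delimited interaction file.
#' @param physical_only drop rows whose experimental system type is not
#'   \code{"physical"} (default \code{TRUE}; only meaningful for the BioGRID
#'   dialect, which records both physical and genetic interactions).
#' @param quiet suppress the load-summary message.
#' @return an interactome graph (see [as_interactome()]).
#' @export
read_interactions <- function(path, physical_only = TRUE, quiet = FALSE) {
  if (!file.exists(path)) {
    stop_spanet(paste0("interaction file not found: ", path), "spanet_io_error")
  }
  first <- readLines(path, n = 1L)
  is_biogrid <- grepl("official symbol", tolower(first), fixed = TRUE)
  if (is_biogrid) {
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             colClasses = "character", quote = "")
    cols <- tolower(trimws(names(tab)))
    need <- c("official symbol interactor a", "official symbol interactor b",
              "experimental system type")
    for (cn in need) {
      if (!cn %in% cols) {
        stop_spanet(paste0("missing required column: ", cn),
                    "spanet_format_error")
      }
    }
    a <- tab[[which(cols == need[1])[1]]]
    b <- tab[[which(cols == need[2])[1]]]
    sys_type <- tolower(tab[[which(cols == need[3])[1]]])
  } else {
    tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                             quote = "")
    if (ncol(tab) < 2L) {
      stop_spanet("edge list must have two tab-separated columns",
                  "spanet_format_error")
    }
    a <- tab[[1L]]
    b <- tab[[2L]]
    sys_type <- rep("physical", length(a))
  }
  n_read <- length(a)
  keep_sys <- if (physical_only) sys_type == "physical" else rep(TRUE, n_read)
  n_nonphysical <- sum(!keep_sys)
  a <- a[keep_sys]; b <- b[keep_sys]
  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  a <- a[!dup]; b <- b[!dup]
  if (length(a) == 0L) {
    stop_spanet("empty interactome: no interactions survived loading",
                "spanet_empty_error")
  }
  g <- as_interactome(cbind(a, b))
  summary <- list(rows_read = n_read, dropped_nonphysical = n_nonphysical,
                  dropped_self = n_self, dropped_duplicate = n_dup,
                  edges = igraph::ecount(g), nodes = igraph::vcount(g))
  if (!quiet) {
    message(sprintf(
      "read_interactions: %d rows -> %d edges / %d nodes (dropped %d non-physical, %d self, %d duplicate)",
      n_read, summary$edges, summary$nodes, n_nonphysical, n_self, n_dup))
  }
  attr(g, "load_summary") <- summary
  g
}

#' Write an interactome to disk
#'
#' The TSV format is a three-column BioGRID-style table (interactor symbols
#' plus an experimental system type of \code{"physical"}) that
#' [read_interactions()] parses back losslessly; GraphML goes through the
#' standard \pkg{igraph} writer.  Node and edge sets survive a round trip
#' exactly.
#'
#' @param g interactome graph.
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"graphml"}.
#' @export
write_network <- function(g, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  g <- validate_interactome(g)
  if (igraph::ecount(g) == 0L) {
    stop_spanet("empty interactome: refusing to write a graph with no edges",
                "spanet_empty_error")
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  ord <- order(el[, 1L], el[, 2L])
  out <- data.frame(
    `Official Symbol Interactor A` = el[ord, 1L],
    `Official Symbol Interactor B` = el[ord, 2L],
    `Experimental System Type` = "physical",
    check.names = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Induce a sub-interactome on a protein set
#'
#' Keeps the proteins in \code{keep} that are present in \code{g} (unknown
#' identifiers are ignored with a warning) together with every edge of
#' \code{g} whose two endpoints are both kept.
#'
#' @param g interactome graph.
#' @param keep character vector of protein identifiers.
#' @return the induced interactome.
#' @export
induce_network <- function(g, keep) {
  g <- validate_interactome(g)
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, igraph::V(g)$name)
  if (length(missing) > 0L) {
    warning(sprintf("%d identifiers not in the network were ignored (e.g. %s)",
                    length(missing), missing[1L]), call. = FALSE)
    keep <- setdiff(keep, missing)
  }
  igraph::induced_subgraph(g, keep)
}

# canonical "a|b" (a < b) edge keys, used by round-trip checks and tests
edge_keys <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0L) return(character())
  sort(paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]), sep = "|"))
}
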