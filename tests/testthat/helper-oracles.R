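# Brute-force oracles, written directly against raw edge lists so they are
# independent of the package's (igraph-backed) code paths.

# named adjacency list from a two-column character edge matrix
bf_adjacency <- function(el, nodes = NULL) {
  nodes <- sort(unique(c(el[, 1L], el[, 2L], nodes)))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) adj[[v]] <- character()
  for (r in seq_len(nrow(el))) {
    a <- el[r, 1L]; b <- el[r, 2L]
    if (a == b) next
    if (!b %in% adj[[a]]) adj[[a]] <- c(adj[[a]], b)
    if (!a %in% adj[[b]]) adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, sort)
}

# every simple path from s to t with exactly L nodes (plain recursion, no
# pruning) -- list of character vectors
bf_simple_paths <- function(adj, s, t, L) {
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (length(path) == L) {
      if (v == t) out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (w in adj[[v]]) if (!w %in% path) walk(c(path, w))
    invisible()
  }
  walk(s)
  out
}

# all-pairs shortest path lengths by repeated relaxation (Floyd-Warshall)
bf_distances <- function(adj) {
  nodes <- names(adj)
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (v in nodes) d[v, adj[[v]]] <- 1
  for (k in nodes) for (i in nodes) for (j in nodes) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# exhaustive betweenness: enumerate every simple path between each unordered
# pair, keep the shortest ones, and accredit interior nodes fractionally
bf_betweenness <- function(adj) {
  nodes <- names(adj)
  bc <- stats::setNames(rep(0, length(nodes)), nodes)
  d <- bf_distances(adj)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    s <- nodes[i]; t <- nodes[j]
    if (!is.finite(d[s, t]) || d[s, t] < 1) next
    geodesics <- bf_simple_paths(adj, s, t, L = d[s, t] + 1)
    for (p in geodesics) {
      interior <- p[-c(1L, length(p))]
      for (v in interior) bc[v] <- bc[v] + 1 / length(geodesics)
    }
  }
  bc
}

# local clustering by triangle counting over neighbor pairs
bf_local_cc <- function(adj) {
  vapply(names(adj), function(v) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2L) return(0)
    tri <- 0L
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
      if (nb[b] %in% adj[[nb[a]]]) tri <- tri + 1L
    }
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

# connected components by union-find over the edge list
bf_components <- function(el, nodes) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (r in seq_len(nrow(el))) {
    ra <- find(el[r, 1L]); rb <- find(el[r, 2L])
    if (ra != rb) parent[[ra]] <- rb
  }
  length(unique(vapply(nodes, find, character(1))))
}

# Erdos-Renyi edge matrix over named nodes (base R only)
random_edge_matrix <- function(n, p, seed) {
  nodes <- sprintf("n%02d", seq_len(n))
  set.seed(seed)
  el <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (stats::runif(1) < p) el <- rbind(el, c(nodes[i], nodes[j]))
  }
  list(nodes = nodes, edges = el)
}

path_graph <- function(nodes) {
  as_interactome(cbind(nodes[-length(nodes)], nodes[-1L]))
}

complete_graph <- function(nodes) {
  as_interactome(t(utils::combn(nodes, 2L)))
}

cycle_graph <- function(nodes) {
  as_interactome(cbind(nodes, c(nodes[-1L], nodes[1L])))
}

star_graph <- function(center, leaves) {
  as_interactome(cbind(center, leaves))
}

# first node pair (lexicographic by index) farther apart than L - 1 edges;
# planting a corridor between such endpoints makes it the only channel of
# node-length L, so planted participation structure is exactly recoverable
find_far_pair <- function(g, L) {
  d <- igraph::distances(g)
  idx <- which(d > L - 1 & upper.tri(d), arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  rownames(d)[c(idx[1L, 1L], idx[1L, 2L])]
}

# small fully-collection-annotated table for expansion tests
uniform_annotations <- function(proteins,
                                p = "GO:P1", f = "GO:F1", c_ = "GO:C1") {
  terms <- lapply(proteins, function(x) {
    list(process = p, `function` = f, component = c_)
  })
  names(terms) <- proteins
  annotation_table(terms)
}
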