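#' Cumulative-histogram decomposition of participation frequencies
#'
#' The key-protein selection machinery.  Given the participation
#' percentages of \code{n} proteins, the frequencies are binned into
#' \code{k = round(sqrt(n))} (half-up, minimum 2) equal-width bins over
#' \code{(0, f_max]}.  With bin counts \eqn{m_i}, cumulative percentages
#' \eqn{M_i} (with \eqn{M_0 = 0} and \eqn{M_k = 100}) and per-bin increments
#' \eqn{D_i = M_i - M_{i-1}}, the fold change of bin \eqn{i} is
#' \eqn{F_i = D_i / D_{i+1}} for \eqn{i = 1, \dots, k-1} (undefined when
#' \eqn{D_{i+1} = 0}).  Bins are ranked by fold change descending (ties to
#' the smaller index) and the first ranked bin whose strict upper tail holds
#' at most 10\% of the proteins becomes the threshold bin; the key set is
#' every protein with frequency strictly above that bin's upper edge.  When
#' no ranked bin qualifies, the fallback takes the top
#' \code{floor(0.10 n)} proteins by frequency (ties by frequency then
#' identifier) and flags the decomposition.
#'
#' The fold change peaks where the cumulative curve flattens, separating the
#' low-participation bulk from the high-participation tail.  The reciprocal
#' reading \eqn{F_i = D_{i+1} / D_i} is available via \code{fold =
#' "growth"}.
#'
#' @param frequencies named numeric vector of participation percentages in
#'   \code{(0, 100]}, one per protein.
#' @param fold \code{"decay"} (default, \eqn{D_i / D_{i+1}}) or
#'   \code{"growth"} (the reciprocal).
#' @return object of class \code{histogram_decomposition}: list with
#'   \code{n}, \code{k}, \code{breaks}, \code{m}, \code{M}, \code{D},
#'   \code{fold_change}, \code{threshold_bin} (NA when the fallback was
#'   taken), \code{keys}, \code{fallback} and a human-readable \code{trail}.
#' @export
decompose_participation <- function(frequencies, fold = c("decay", "growth")) {
  fold <- match.arg(fold)
  f <- frequencies
  if (length(f) == 0L) {
    stop_spanet("`frequencies` must be nonempty", "spanet_parameter_error")
  }
  if (is.null(names(f)) || any(!nzchar(names(f)))) {
    stop_spanet("`frequencies` must be named by protein",
                "spanet_parameter_error")
  }
  if (any(!is.finite(f)) || any(f <= 0) || any(f > 100)) {
    stop_spanet("frequencies must lie in (0, 100]", "spanet_parameter_error")
  }
  n <- length(f)
  k <- max(2L, as.integer(round_half_up(sqrt(n))))
  f_max <- max(f)
  width <- f_max / k
  breaks <- width * seq_len(k)           # upper edges of the k bins
  # left-open right-closed bins over (0, f_max]
  bin <- pmin(k, pmax(1L, as.integer(ceiling(f / width - 1e-9))))
  m <- tabulate(bin, nbins = k)
  M <- 100 * cumsum(m) / n
  D <- diff(c(0, M))
  trail <- character()
  fold_change <- rep(NA_real_, k - 1L)
  for (i in seq_len(k - 1L)) {
    num <- if (fold == "decay") D[i] else D[i + 1L]
    den <- if (fold == "decay") D[i + 1L] else D[i]
    fold_change[i] <- if (den == 0) NA_real_ else num / den
  }
  tail_size <- vapply(seq_len(k - 1L),
                      function(i) sum(f > breaks[i] + 1e-9), integer(1))
  limit <- 0.10 * n
  candidates <- which(!is.na(fold_change))
  candidates <- candidates[order(-fold_change[candidates], candidates)]
  threshold_bin <- NA_integer_
  for (i in candidates) {
    if (tail_size[i] <= limit + 1e-9) {
      threshold_bin <- i
      break
    }
    trail <- c(trail, sprintf(
      "bin %d (fold change %.3g) rejected: %d proteins above its edge exceed 10%% of %d",
      i, fold_change[i], tail_size[i], n))
  }
  fallback <- is.na(threshold_bin)
  if (!fallback) {
    keys <- names(f)[f > breaks[threshold_bin] + 1e-9]
    keys <- keys[order(-f[keys], keys)]
    trail <- c(trail, sprintf(
      "threshold bin %d (upper edge %.4g): %d key proteins",
      threshold_bin, breaks[threshold_bin], length(keys)))
  } else {
    n_keys <- floor(limit)
    ord <- order(-f, names(f))
    keys <- names(f)[ord][seq_len(n_keys)]
    trail <- c(trail, sprintf(
      "no qualifying bin: fallback to top %d proteins by frequency", n_keys))
  }
  structure(
    list(n = n, k = k, breaks = breaks, m = m, M = M, D = D,
         fold_change = fold_change, threshold_bin = threshold_bin,
         keys = keys, fallback = fallback, trail = trail,
         frequencies = f),
    class = "histogram_decomposition"
  )
}

#' @export
print.histogram_decomposition <- function(x, ...) {
  cat(sprintf(
    "<histogram_decomposition> n = %d, k = %d bins, threshold bin %s, %d keys%s\n",
    x$n, x$k, ifelse(is.na(x$threshold_bin), "none", x$threshold_bin),
    length(x$keys), if (x$fallback) " (fallback)" else ""))
  invisible(x)
}

#' Step-specific key proteins by iterative bait-and-hit decomposition
#'
#' For a spectrum of node-length-L paths, the positional participation of
#' the proteins at position 2 is decomposed ([decompose_participation()]) to
#' yield the keys of the first step.  These keys are then used as baits:
#' only paths whose position-2 member is a key are retained, and the
#' procedure is repeated at position 3 on the reduced subset, through
#' position L-1.  For L = 6 this yields the four step-specific key sets of
#' the four intermediate positions.  When a step's decomposition returns an
#' empty key set (degenerate histogram with no admissible threshold), the
#' histogram provides no basis for exclusion: every protein observed at that
#' position is retained as a key and the step is flagged in the audit trail.
#'
#' @param spectrum a nonempty [enumerate_paths()] spectrum.
#' @param fold fold-change direction, see [decompose_participation()].
#' @return object of class \code{stepwise_keys}: list with \code{keys} (list
#'   of per-step character vectors, one per intermediate position),
#'   \code{decompositions}, \code{subset_sizes} (paths remaining after each
#'   filtering), \code{degenerate_steps}, \code{input}, \code{output}.
#' @export
stepwise_keys <- function(spectrum, fold = c("decay", "growth")) {
  fold <- match.arg(fold)
  stopifnot(inherits(spectrum, "path_spectrum"))
  if (nrow(spectrum$paths) == 0L) {
    stop_spanet("key-protein extraction requires a nonempty spectrum",
                "spanet_parameter_error")
  }
  L <- spectrum$L
  positions <- 2:(L - 1L)
  subset <- spectrum$paths
  keys <- list()
  decomps <- list()
  sizes <- integer()
  degenerate <- integer()
  for (s in seq_along(positions)) {
    pos <- positions[s]
    np <- nrow(subset)
    counts <- table(subset[, pos])
    freq <- 100 * as.numeric(counts) / np
    names(freq) <- names(counts)
    dec <- decompose_participation(freq, fold = fold)
    step_keys <- dec$keys
    if (length(step_keys) == 0L) {
      step_keys <- sort(names(freq))
      degenerate <- c(degenerate, s)
    }
    keep <- subset[, pos] %in% step_keys
    subset <- subset[keep, , drop = FALSE]
    if (nrow(subset) == 0L) {
      stop_spanet(sprintf("filtered path subset became empty at step %d", s),
                  "spanet_keyprotein_error")
    }
    keys[[s]] <- step_keys
    decomps[[s]] <- dec
    sizes[s] <- nrow(subset)
  }
  structure(
    list(keys = keys, decompositions = decomps, subset_sizes = sizes,
         degenerate_steps = degenerate,
         input = spectrum$input, output = spectrum$output, L = L),
    class = "stepwise_keys"
  )
}

#' @export
print.stepwise_keys <- function(x, ...) {
  cat(sprintf("<stepwise_keys> %s -> %s: %s keys per step; subset sizes %s\n",
              x$input, x$output,
              paste(lengths(x$keys), collapse = "/"),
              paste(x$subset_sizes, collapse = "/")))
  invisible(x)
}

#' Globally important proteins of a path spectrum
#'
#' The classical global analysis: the participation percentage of every
#' non-endpoint member (endpoints are excluded, being trivially present in
#' 100\% of paths) is decomposed with the participation histogram, or the
#' top fraction by participation is taken directly.
#'
#' @param spectrum a nonempty [enumerate_paths()] spectrum.
#' @param method \code{"histogram"} (default) or \code{"top-fraction"}.
#' @param fraction fraction for the \code{"top-fraction"} method.
#' @param fold fold-change direction for the histogram method.
#' @return character vector of important proteins (never the endpoints).
#' @export
global_importants <- function(spectrum, method = c("histogram", "top-fraction"),
                              fraction = 0.1, fold = c("decay", "growth")) {
  method <- match.arg(method)
  fold <- match.arg(fold)
  stopifnot(inherits(spectrum, "path_spectrum"))
  if (nrow(spectrum$paths) == 0L) {
    stop_spanet("global importance requires a nonempty spectrum",
                "spanet_parameter_error")
  }
  freq <- participation(spectrum, "global")
  freq <- freq[!names(freq) %in% c(spectrum$input, spectrum$output)]
  if (length(freq) == 0L) return(character())
  if (method == "histogram") {
    decompose_participation(freq, fold = fold)$keys
  } else {
    n_keys <- max(1L, floor(fraction * length(freq)))
    names(freq)[order(-freq, names(freq))][seq_len(n_keys)]
  }
}

#' Assemble the heart network from per-branch key sets
#'
#' Pools the step-specific key sets of all branches, unites them with the
#' input and output proteins, and induces the subgraph of the analyzed
#' network on that member set.  Per-pair path coverage is the percentage of
#' the branch's full spectrum whose intermediate members all lie in the
#' heart member set.
#'
#' @param branches list of [stepwise_keys()] results.
#' @param inputs,outputs character vectors of input and output proteins.
#' @param g the interactome the branches were computed on.
#' @param spectra optional list of the corresponding full
#'   [enumerate_paths()] spectra (same order as \code{branches}) for the
#'   coverage check.
#' @return object of class \code{heart_network}: list with \code{members},
#'   \code{network} and \code{coverage} (data frame, NULL when no spectra
#'   are supplied).
#' @export
assemble_heart <- function(branches, inputs, outputs, g, spectra = NULL) {
  g <- validate_interactome(g)
  pooled <- unlist(lapply(branches, function(b) unlist(b$keys)),
                   use.names = FALSE)
  members <- sort(unique(c(pooled, as.character(inputs),
                           as.character(outputs))))
  members <- intersect(members, igraph::V(g)$name)
  heart <- induce_network(g, members)
  coverage <- NULL
  if (!is.null(spectra)) {
    coverage <- do.call(rbind, lapply(spectra, function(s) {
      np <- nrow(s$paths)
      covered <- if (np == 0L) 0 else {
        inter <- s$paths[, 2:(s$L - 1L), drop = FALSE]
        100 * mean(apply(inter, 1L, function(r) all(r %in% members)))
      }
      data.frame(input = s$input, output = s$output, n_paths = np,
                 coverage_pct = covered)
    }))
    rownames(coverage) <- NULL
  }
  structure(list(members = members, network = heart, coverage = coverage),
            class = "heart_network")
}

#' @export
print.heart_network <- function(x, ...) {
  cat(sprintf("<heart_network> %d proteins, %d interactions\n",
              length(x$members), igraph::ecount(x$network)))
  if (!is.null(x$coverage)) {
    cat(sprintf("  path coverage: %.1f-%.1f%% across %d branches\n",
                min(x$coverage$coverage_pct), max(x$coverage$coverage_pct),
                nrow(x$coverage)))
  }
  invisible(x)
}
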