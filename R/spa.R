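#' Build the annotation collection of a core protein set
#'
#' The annotation collection is the aspect-wise union of the core proteins'
#' GO terms, with the three root "unknown" sentinel terms always included so
#' that poorly annotated candidates are never excluded solely for lack of
#' curated data.
#'
#' @param core character vector of core protein identifiers.
#' @param annotations an [annotation_table()] covering every core protein.
#' @return object of class \code{annotation_collection}: a list with term
#'   sets \code{process}, \code{function} and \code{component}.
#' @export
build_collection <- function(core, annotations) {
  core <- as.character(core)
  if (length(core) == 0L) stop("`core` must be nonempty", call. = FALSE)
  stopifnot(inherits(annotations, "annotation_table"))
  missing <- setdiff(core, annotated_proteins(annotations))
  if (length(missing) > 0L) {
    stop_spanet(paste0("core protein(s) missing from the annotation table: ",
                       paste(missing, collapse = ", ")),
                "spanet_parameter_error")
  }
  sent <- go_unknown_terms()
  coll <- lapply(aspect_names(), function(a) {
    pooled <- unlist(lapply(core, function(p) annotations$terms[[p]][[a]]),
                     use.names = FALSE)
    sort(unique(c(pooled, unname(sent[[a]]))))
  })
  names(coll) <- aspect_names()
  structure(coll, class = "annotation_collection")
}

#' @export
print.annotation_collection <- function(x, ...) {
  cat(sprintf("<annotation_collection> process: %d, function: %d, component: %d terms\n",
              length(x$process), length(x$`function`), length(x$component)))
  invisible(x)
}

#' Test a candidate protein against an annotation collection
#'
#' Under the default \code{"any"} (any-per-aspect) mode a protein is
#' permissible when each of its three aspect term sets shares at least one
#' term with the collection's matching set; under \code{"all"} every term in
#' all three aspects must belong to the collection.  Sentinel (root
#' "unknown") terms always match, and a protein absent from the annotation
#' table is sentinel-filled in all aspects.
#'
#' @param protein protein identifier.
#' @param annotations an [annotation_table()].
#' @param collection an annotation collection from [build_collection()].
#' @param mode \code{"any"} or \code{"all"}.
#' @return logical scalar; attribute \code{"failed_aspects"} lists the
#'   aspects that failed the criterion.
#' @export
is_permissible <- function(protein, annotations, collection,
                           mode = c("any", "all")) {
  mode <- match.arg(mode)
  tt <- protein_terms(annotations, protein)
  failed <- character()
  for (a in aspect_names()) {
    hit <- tt[[a]] %in% collection[[a]]
    ok <- if (mode == "any") any(hit) else all(hit)
    if (!ok) failed <- c(failed, a)
  }
  structure(length(failed) == 0L, failed_aspects = failed)
}

#' Expand a core protein set into a process-specific network
#'
#' Iterated neighbor admission: starting from the core, each cycle examines
#' the proteins adjacent to the current member set that have not been
#' examined before and admits those whose annotations pass the collection
#' criterion ([is_permissible()]).  Expansion stops at the fixed point where
#' no new protein is admitted.  The returned network is the induced subgraph
#' of \code{g} on the member set, i.e. it retains all source edges among
#' members, not only the discovery edges.
#'
#' @param core character vector of core protein identifiers (all must be
#'   nodes of \code{g}).
#' @param g interactome graph to expand within.
#' @param annotations an [annotation_table()].
#' @param mode permissibility mode, see [is_permissible()].
#' @return list with elements \code{network} (induced interactome),
#'   \code{members} (character vector) and \code{log} (one row per
#'   iteration: candidates examined, admitted, rejected counts by aspect,
#'   cumulative node count).
#' @export
spa_expand <- function(core, g, annotations, mode = c("any", "all")) {
  mode <- match.arg(mode)
  g <- validate_interactome(g)
  core <- unique(as.character(core))
  absent <- setdiff(core, igraph::V(g)$name)
  if (length(absent) > 0L) {
    stop_spanet(paste0("core protein(s) absent from the interactome: ",
                       paste(absent, collapse = ", ")),
                "spanet_parameter_error")
  }
  collection <- build_collection(core, annotations)
  members <- core
  examined <- character()  # candidates already decided (admission is a
                           # property of the candidate's annotations only)
  log_rows <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    nbrs <- igraph::V(g)$name[
      unique(unlist(igraph::adjacent_vertices(g, members)))
    ]
    candidates <- sort(setdiff(nbrs, c(members, examined)))
    admitted <- character()
    rej_aspect <- c(process = 0L, `function` = 0L, component = 0L)
    for (p in candidates) {
      ok <- is_permissible(p, annotations, collection, mode)
      if (isTRUE(as.logical(ok))) {
        admitted <- c(admitted, p)
      } else {
        for (a in attr(ok, "failed_aspects")) {
          rej_aspect[[a]] <- rej_aspect[[a]] + 1L
        }
      }
    }
    examined <- c(examined, candidates)
    members <- c(members, admitted)
    log_rows[[iter]] <- data.frame(
      iteration = iter,
      candidates = length(candidates),
      admitted = length(admitted),
      rejected = length(candidates) - length(admitted),
      rejected_process = unname(rej_aspect[["process"]]),
      rejected_function = unname(rej_aspect[["function"]]),
      rejected_component = unname(rej_aspect[["component"]]),
      cumulative_nodes = length(members)
    )
    if (length(admitted) == 0L) break
  }
  list(
    network = induce_network(g, members),
    members = sort(members),
    log = do.call(rbind, log_rows)
  )
}
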