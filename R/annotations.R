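#' Root "unknown" Gene Ontology terms
#'
#' The three GO aspect roots act as sentinel terms for proteins whose
#' annotation in an aspect is missing.  They are always members of every
#' annotation collection, so an unannotated aspect never causes a protein to
#' be excluded solely for lack of literature data.
#'
#' @return named character vector with elements \code{process},
#'   \code{function} and \code{component}.
#' @export
go_unknown_terms <- function() {
  c(process = "biological_process",
    `function` = "molecular_function",
    component = "cellular_component")
}

aspect_names <- function() c("process", "function", "component")

#' Construct an annotation table
#'
#' Per-protein GO term sets in the three aspects (biological process,
#' molecular function, cellular component).  Every protein has all three
#' aspect sets defined; an empty aspect set is replaced by that aspect's root
#' "unknown" sentinel term.
#'
#' @param terms named list: protein identifier -> list with character vectors
#'   \code{process}, \code{function}, \code{component} (any may be missing or
#'   empty; sentinels are filled in).
#' @return an object of class \code{annotation_table}.
#' @export
annotation_table <- function(terms = list()) {
  sent <- go_unknown_terms()
  proteins <- names(terms)
  if (length(terms) > 0L && (is.null(proteins) || any(!nzchar(proteins)))) {
    stop("`terms` must be a named list keyed by protein identifier",
         call. = FALSE)
  }
  filled <- lapply(terms, function(tt) {
    out <- lapply(aspect_names(), function(a) {
      v <- unique(as.character(tt[[a]] %||% character()))
      v <- v[nzchar(v) & !is.na(v)]
      if (length(v) == 0L) unname(sent[[a]]) else v
    })
    names(out) <- aspect_names()
    out
  })
  structure(list(terms = filled), class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("<annotation_table> %d proteins, three GO aspects\n",
              length(x$terms)))
  invisible(x)
}

annotated_proteins <- function(annotations) names(annotations$terms)

# Aspect sets for one protein; absent proteins are sentinel-filled in all
# three aspects (they pass any collection check by the unknown-term rule).
protein_terms <- function(annotations, protein) {
  tt <- annotations$terms[[protein]]
  if (is.null(tt)) {
    sent <- go_unknown_terms()
    tt <- list(process = unname(sent[["process"]]),
               `function` = unname(sent[["function"]]),
               component = unname(sent[["component"]]))
  }
  tt
}

#' Read a GO annotation file
#'
#' Accepts a GAF-style subset: a tab-delimited table with protein symbol,
#' aspect code (\code{P}, \code{F} or \code{C}) and GO term identifier
#' columns.  A header row is tolerated (detected by an aspect field outside
#' \code{P/F/C}).  Proteins listed in \code{proteins} but absent from the
#' file receive all-sentinel annotations.
#'
#' @param path path to the annotation file.
#' @param proteins optional character vector (e.g. the node set of an
#'   interactome) guaranteeing an entry for each listed protein.
#' @return an [annotation_table()].
#' @export
read_annotations <- function(path, proteins = NULL) {
  if (!file.exists(path)) {
    stop_spanet(paste0("annotation file not found: ", path), "spanet_io_error")
  }
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           quote = "")
  if (ncol(tab) < 3L) {
    stop_spanet("annotation file must have three tab-separated columns",
                "spanet_format_error")
  }
  offset <- 0L
  if (nrow(tab) > 0L && !toupper(trimws(tab[1L, 2L])) %in% c("P", "F", "C")) {
    tab <- tab[-1L, , drop = FALSE]  # header row
    offset <- 1L
  }
  aspect_code <- toupper(trimws(tab[[2L]]))
  bad <- which(!aspect_code %in% c("P", "F", "C"))
  if (length(bad) > 0L) {
    stop_spanet(sprintf("unknown aspect code '%s' at row %d",
                        tab[bad[1L], 2L], bad[1L] + offset),
                "spanet_format_error")
  }
  aspect <- c(P = "process", F = "function", C = "component")[aspect_code]
  prot <- trimws(tab[[1L]])
  term <- trimws(tab[[3L]])
  terms <- list()
  for (p in unique(c(prot, as.character(proteins)))) {
    rows <- prot == p
    terms[[p]] <- list(
      process = term[rows & aspect == "process"],
      `function` = term[rows & aspect == "function"],
      component = term[rows & aspect == "component"]
    )
  }
  annotation_table(terms)
}

#' Write an annotation table as a three-column TSV
#'
#' One row per (protein, aspect code, term); the inverse of
#' [read_annotations()].
#'
#' @param annotations an [annotation_table()].
#' @param path output file path.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_table"))
  code <- c(process = "P", `function` = "F", component = "C")
  rows <- list()
  for (p in sort(names(annotations$terms))) {
    tt <- annotations$terms[[p]]
    for (a in aspect_names()) {
      for (tm in sort(tt[[a]])) {
        rows[[length(rows) + 1L]] <- c(p, code[[a]], tm)
      }
    }
  }
  mat <- do.call(rbind, rows)
  utils::write.table(mat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
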