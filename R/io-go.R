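#' Read query-to-GO mappings with ancestor closure
#'
#' Loads two sidecar tables: a query annotation table
#' (`query_id<TAB>GO:a;GO:b`) and an ancestor table
#' (`GO:a<TAB>GO:p1;GO:p2`, terms with no row are roots).  The ancestor
#' relation is checked for cycles, the transitive closure is precomputed,
#' and every query's term set is closed over ancestors, so annotation with a
#' term implies annotation with all of its parents (each counted once per
#' query).
#'
#' @param query_path path to the query annotation TSV.
#' @param ancestor_path path to the ancestor TSV.
#' @param labels optional named character vector of human-readable term
#'   labels.
#' @return an object of class `go_annotation`: a list with
#'   `query_terms` (named list of ancestor-closed term vectors),
#'   `ancestors` (named list, transitive closure per term) and `labels`.
#' @export
read_go_mapping <- function(query_path, ancestor_path, labels = NULL) {
  qmap <- read_two_col_sets(query_path, "query annotation")
  amap <- read_two_col_sets(ancestor_path, "ancestor")
  go_annotation(qmap, amap, labels)
}

#' Build a GO annotation object from in-memory mappings
#'
#' @param query_terms named list: query id to character vector of directly
#'   assigned term ids.
#' @param parents named list: term id to character vector of direct parent
#'   term ids; terms absent from the list are roots.
#' @param labels optional named character vector of term labels.
#' @return a `go_annotation` object (see [read_go_mapping()]).
#' @export
go_annotation <- function(query_terms, parents, labels = NULL) {
  closure <- ancestor_closure(parents)
  query_closed <- lapply(query_terms, function(terms) {
    sort(unique(c(terms, unlist(closure[intersect(terms, names(closure))],
                                use.names = FALSE))))
  })
  structure(list(query_terms = query_closed, ancestors = closure,
                 labels = labels),
            class = "go_annotation")
}

# Transitive closure of the parent relation with cycle detection
# (iterative DFS with colour marking; a back edge is reported as a cycle).
ancestor_closure <- function(parents) {
  terms <- names(parents)
  closure <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())  # "visiting" / "done"
  visit <- function(term, path) {
    st <- state[[term]]
    if (identical(st, "done")) return(closure[[term]])
    if (identical(st, "visiting")) {
      cyc <- c(path[which(path == term)[1L]:length(path)], term)
      stop("cycle in ancestor table: ", paste(cyc, collapse = " -> "))
    }
    state[[term]] <- "visiting"
    direct <- parents[[term]]
    anc <- character()
    for (p in direct) {
      anc <- c(anc, p,
               if (p %in% terms) visit(p, c(path, term)) else character())
    }
    anc <- sort(unique(anc))
    closure[[term]] <- anc
    state[[term]] <- "done"
    anc
  }
  for (t in terms) visit(t, character())
  out <- lapply(terms, function(t) closure[[t]])
  names(out) <- terms
  out
}

read_two_col_sets <- function(path, what) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1L]
    stop(what, " table line ", bad, ": expected 2 tab-separated columns")
  }
  keys <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(keys)) {
    stop(what, " table has duplicate key: ", keys[duplicated(keys)][1L])
  }
  vals <- lapply(fields, function(f) {
    v <- strsplit(f[[2L]], ";", fixed = TRUE)[[1L]]
    v[nzchar(trimws(v))]
  })
  names(vals) <- keys
  vals
}
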