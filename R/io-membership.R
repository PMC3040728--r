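#' Read an isotig/isogroup/contig membership table
#'
#' The membership sidecar serializes the assembler's hierarchy: each row is
#' `isotig_id<TAB>isogroup_id<TAB>contig1,contig2,...`, the contig list
#' giving the ordered path of contigs making up that isotig.
#'
#' @param path path to a TSV file (`.gz` accepted) or connection.
#' @return a `data.frame` with columns `isotig_id`, `isogroup_id` and a
#'   list column `contig_ids`.
#' @export
read_membership <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    bad <- which(nf != 3L)[1L]
    stop("line ", bad, ": expected 3 tab-separated columns, found ", nf[bad])
  }
  m <- do.call(rbind, fields)
  contigs <- strsplit(m[, 3L], ",", fixed = TRUE)
  contigs <- lapply(contigs, function(x) x[nzchar(trimws(x))])
  tab <- data.frame(isotig_id = m[, 1L], isogroup_id = m[, 2L],
                    stringsAsFactors = FALSE)
  tab$contig_ids <- contigs
  validate_membership(tab)
}

validate_membership <- function(tab) {
  if (anyDuplicated(tab$isotig_id)) {
    stop("duplicate isotig id: ", tab$isotig_id[duplicated(tab$isotig_id)][1L])
  }
  empty <- lengths(tab$contig_ids) == 0L
  if (any(empty)) {
    stop("isotig '", tab$isotig_id[which(empty)[1L]], "' has an empty contig list")
  }
  tab
}

#' Write a membership table
#'
#' @param membership a membership `data.frame` ([read_membership()] layout).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_membership <- function(membership, path) {
  out <- paste(membership$isotig_id, membership$isogroup_id,
               vapply(membership$contig_ids, paste, character(1L),
                      collapse = ","),
               sep = "\t")
  con <- open_out(path)
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}
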