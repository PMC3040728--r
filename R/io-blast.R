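#' Read BLAST tabular output (outfmt 6)
#'
#' Parses the standard 12-column tab-separated BLAST output, optionally with
#' a 13th subject-length (`slen`) column.  Coordinates are normalized so
#' that `q_start <= q_end` and `s_start <= s_end`; the original orientation
#' of each axis is recorded in `q_strand` / `s_strand` (`"plus"` or
#' `"minus"`).  Coordinates are 1-based and inclusive throughout.
#'
#' @param path path to a tab-separated hit table (`.gz` accepted) or a
#'   connection.
#' @param expect_subject_len if `TRUE`, a 13th column holding the full
#'   subject length is required and stored in `subject_len`; otherwise
#'   `subject_len` is `NA`.
#' @return a `data.frame` of hits in row order with columns `query_id`,
#'   `subject_id`, `pct_identity`, `aln_len`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`,
#'   `subject_len`, `q_strand`, `s_strand`.
#' @export
read_blast_tab <- function(path, expect_subject_len = FALSE) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_blast_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  want <- if (expect_subject_len) 13L else 12L
  nf <- lengths(fields)
  if (any(nf != want)) {
    bad <- which(nf != want)[1L]
    stop("line ", bad, ": expected ", want, " columns, found ", nf[bad])
  }
  m <- do.call(rbind, fields)
  num <- function(j, what, integer = FALSE) {
    x <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(x)) {
      stop("line ", which(is.na(x))[1L], ": non-numeric value '",
           m[which(is.na(x))[1L], j], "' in ", what, " column")
    }
    if (integer) as.integer(x) else x
  }
  hits <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    pct_identity = num(3L, "percent-identity"),
    aln_len = num(4L, "alignment-length", TRUE),
    mismatches = num(5L, "mismatch", TRUE),
    gap_opens = num(6L, "gap-open", TRUE),
    q_start = num(7L, "q_start", TRUE), q_end = num(8L, "q_end", TRUE),
    s_start = num(9L, "s_start", TRUE), s_end = num(10L, "s_end", TRUE),
    evalue = num(11L, "evalue"), bitscore = num(12L, "bitscore"),
    subject_len = if (expect_subject_len) num(13L, "subject-length", TRUE)
                  else NA_integer_,
    stringsAsFactors = FALSE)
  if (any(hits$evalue < 0)) {
    stop("line ", which(hits$evalue < 0)[1L], ": negative e-value")
  }
  if (any(hits$aln_len < 1L)) {
    stop("line ", which(hits$aln_len < 1L)[1L], ": alignment length < 1")
  }
  normalize_hit_coords(hits)
}

normalize_hit_coords <- function(hits) {
  qrev <- hits$q_start > hits$q_end
  srev <- hits$s_start > hits$s_end
  hits$q_strand <- ifelse(qrev, "minus", "plus")
  hits$s_strand <- ifelse(srev, "minus", "plus")
  qs <- pmin(hits$q_start, hits$q_end)
  qe <- pmax(hits$q_start, hits$q_end)
  ss <- pmin(hits$s_start, hits$s_end)
  se <- pmax(hits$s_start, hits$s_end)
  hits$q_start <- qs; hits$q_end <- qe
  hits$s_start <- ss; hits$s_end <- se
  hits
}

#' Write a hit table back to BLAST tabular text
#'
#' The inverse of [read_blast_tab()]: minus-strand rows are written with
#' their original (descending) coordinate order restored, so a read/write
#' round trip preserves the text fields.
#'
#' @param hits a hit table from [read_blast_tab()].
#' @param path output path.
#' @param subject_len include the 13th `slen` column.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path, subject_len = FALSE) {
  qs <- ifelse(hits$q_strand == "minus", hits$q_end, hits$q_start)
  qe <- ifelse(hits$q_strand == "minus", hits$q_start, hits$q_end)
  ss <- ifelse(hits$s_strand == "minus", hits$s_end, hits$s_start)
  se <- ifelse(hits$s_strand == "minus", hits$s_start, hits$s_end)
  cols <- list(hits$query_id, hits$subject_id,
               format_blast_num(hits$pct_identity), hits$aln_len,
               hits$mismatches, hits$gap_opens, qs, qe, ss, se,
               format_blast_num(hits$evalue),
               format_blast_num(hits$bitscore))
  if (subject_len) cols <- c(cols, list(hits$subject_len))
  out <- do.call(paste, c(cols, sep = "\t"))
  con <- open_out(path)
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

format_blast_num <- function(x) {
  ifelse(x == floor(x) & abs(x) < 1e15 & x != 0 | x == 0,
         format(x, scientific = FALSE, trim = TRUE),
         format(x, trim = TRUE))
}

empty_blast_table <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pct_identity = numeric(), aln_len = integer(),
             mismatches = integer(), gap_opens = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             evalue = numeric(), bitscore = numeric(),
             subject_len = integer(),
             q_strand = character(), s_strand = character(),
             stringsAsFactors = FALSE)
}
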