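#' Read a FASTA file into a sequence table
#'
#' Parses plain or gzip-compressed FASTA into a data frame with one row per
#' record.  The header text after the first whitespace is kept as the record
#' description.  Residues are validated against the alphabet implied by
#' `role`: nucleotide roles accept the IUPAC nucleotide codes, the
#' `reference_protein` role accepts the 20 amino acids plus `X` and `*`.
#'
#' @param path path to a FASTA file (`.gz` accepted), or a connection.
#' @param role sequence class of every record in the file; one of
#'   `"isotig"`, `"cap3_contig"`, `"cap3_singlet"`, `"read"`,
#'   `"reference_protein"`, `"reference_mrna"`.
#' @return a `data.frame` with columns `id`, `description`, `residues`,
#'   `role`, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a d1", "AC", "GT", ">b", "TTTT"), tf)
#' read_fasta(tf, role = "read")
#' @export
read_fasta <- function(path, role = c("read", "isotig", "cap3_contig",
                                      "cap3_singlet", "reference_protein",
                                      "reference_mrna")) {
  role <- match.arg(role)
  lines <- read_text_lines(path)
  if (length(lines) == 0L) {
    warning("empty FASTA stream: ", deparse(substitute(path)))
    return(empty_seq_table(role))
  }
  is_header <- startsWith(lines, ">")
  nonblank <- nzchar(trimws(lines))
  if (any(nonblank & !is_header) && !is_header[which(nonblank)[1L]]) {
    stop("FASTA parse error at line ", which(nonblank)[1L],
         ": sequence body before any header")
  }
  if (!any(is_header)) {
    stop("FASTA parse error: no header lines found")
  }
  hdr_idx <- which(is_header)
  header <- sub("^>", "", lines[hdr_idx])
  id <- sub("\\s.*$", "", header)
  description <- ifelse(grepl("\\s", header),
                        sub("^\\S+\\s+", "", header), "")
  if (any(!nzchar(id))) {
    stop("FASTA parse error at line ", hdr_idx[which(!nzchar(id))[1L]],
         ": empty record id")
  }
  if (anyDuplicated(id)) {
    stop("duplicate FASTA id: ", id[duplicated(id)][1L])
  }
  # assign body lines to the preceding header
  grp <- findInterval(seq_along(lines), hdr_idx)
  body <- lines[!is_header & nonblank]
  body_grp <- grp[!is_header & nonblank]
  residues <- vapply(seq_along(hdr_idx), function(i) {
    paste(body[body_grp == i], collapse = "")
  }, character(1L))
  if (any(!nzchar(residues))) {
    stop("FASTA record with no residues: ", id[which(!nzchar(residues))[1L]])
  }
  validate_alphabet(residues, role, id)
  data.frame(id = id, description = description, residues = toupper(residues),
             role = role, stringsAsFactors = FALSE)
}

#' Write a sequence table to FASTA
#'
#' @param seqs a data frame as returned by [read_fasta()] (columns `id`,
#'   `description`, `residues`).
#' @param path output file path (`.gz` accepted).
#' @param width line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  desc <- if ("description" %in% names(seqs)) seqs$description else ""
  con <- open_out(path)
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    hdr <- if (nzchar(desc[i])) paste(seqs$id[i], desc[i]) else seqs$id[i]
    writeLines(paste0(">", hdr), con)
    body <- seqs$residues[i]
    starts <- seq(1L, nchar(body), by = width)
    writeLines(substring(body, starts, pmin(starts + width - 1L, nchar(body))),
               con)
  }
  invisible(path)
}

nt_roles <- c("isotig", "cap3_contig", "cap3_singlet", "read",
              "reference_mrna")

validate_alphabet <- function(residues, role, ids) {
  pattern <- if (role %in% nt_roles) {
    "^[ACGTUNRYSWKMBDHVacgtunryswkmbdhv]+$"
  } else {
    "^[ACDEFGHIKLMNPQRSTVWYXacdefghiklmnpqrstvwyx*]+$"
  }
  bad <- !grepl(pattern, residues)
  if (any(bad)) {
    stop("record '", ids[which(bad)[1L]], "' contains characters outside the ",
         if (role %in% nt_roles) "nucleotide" else "amino-acid",
         " alphabet for role '", role, "'")
  }
  invisible(TRUE)
}

empty_seq_table <- function(role = "read") {
  data.frame(id = character(), description = character(),
             residues = character(), role = character(),
             stringsAsFactors = FALSE)
}

read_text_lines <- function(path) {
  if (inherits(path, "connection")) return(readLines(path, warn = FALSE))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

#' Convert assembler-style FASTA headers to a membership table
#'
#' Convenience converter for headers of the form
#' `isotigNNNNN ... isogroupNNNNN`: extracts the isotig and isogroup tokens
#' so a membership sidecar table can be built when none was exported by the
#' assembler.  Contig composition is not recoverable from headers and is set
#' to a single pseudo-contig named after the isotig.
#'
#' @param seqs a sequence table whose `id`/`description` carry
#'   `isotig`/`isogroup` tokens.
#' @return a membership `data.frame` (`isotig_id`, `isogroup_id`,
#'   `contig_ids` list column).
#' @export
membership_from_headers <- function(seqs) {
  text <- paste(seqs$id, seqs$description)
  iso <- regmatches(text, regexpr("isotig\\d+", text))
  grp <- regmatches(text, regexpr("isogroup\\d+", text))
  if (length(iso) != nrow(seqs) || length(grp) != nrow(seqs)) {
    stop("not every header carries both an isotig and an isogroup token")
  }
  data.frame(isotig_id = iso, isogroup_id = grp,
             contig_ids = I(as.list(paste0("ctg_", iso))),
             stringsAsFactors = FALSE)
}
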