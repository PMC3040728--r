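#' Assemble the pieces of an assembly into one object
#'
#' An `assembly_set` bundles the assembler's hierarchy (membership table),
#' the isotig sequences, per-contig composition statistics, and the
#' unassembled singletons.  Contigs are stretches of assembled reads free of
#' branching conflicts (exons or co-transcribed exon sets); isotigs are
#' continuous paths through contigs (transcripts); isogroups are the isotig
#' sets built from one contig set (genes).
#'
#' @param membership a membership `data.frame` ([read_membership()]).
#' @param isotig_seqs sequence table for the isotigs ([read_fasta()]).
#' @param contig_info `data.frame` with columns `contig_id`, `length`
#'   (bp), `n_reads`, `read_bp` (total bases of the constituent reads).
#' @param singleton_seqs optional sequence table of unassembled reads.
#' @return an object of class `assembly_set`.
#' @export
assembly_set <- function(membership, isotig_seqs,
                         contig_info = NULL, singleton_seqs = NULL) {
  membership <- validate_membership(membership)
  if (is.null(singleton_seqs)) singleton_seqs <- empty_seq_table()
  if (is.null(contig_info)) {
    contig_info <- data.frame(contig_id = character(), length = integer(),
                              n_reads = integer(), read_bp = numeric(),
                              stringsAsFactors = FALSE)
  }
  missing_seq <- setdiff(membership$isotig_id, isotig_seqs$id)
  if (length(missing_seq)) {
    stop("isotig without sequence: ", missing_seq[1L])
  }
  if (nrow(contig_info)) {
    referenced <- unique(unlist(membership$contig_ids, use.names = FALSE))
    absent <- setdiff(referenced, contig_info$contig_id)
    if (length(absent)) {
      stop("contig referenced by an isotig but absent from contig_info: ",
           absent[1L])
    }
    stopifnot(all(contig_info$length >= 1L),
              all(contig_info$read_bp >= contig_info$n_reads))
  }
  structure(list(membership = membership, isotig_seqs = isotig_seqs,
                 contig_info = contig_info, singleton_seqs = singleton_seqs),
            class = "assembly_set")
}

#' N50 of a set of sequence lengths
#'
#' The length at which, walking the lengths in decreasing order, the
#' cumulative base count first reaches at least half of the total: 50% of
#' all bases lie in sequences of at least this length.
#'
#' @param lengths positive sequence lengths in bp.
#' @return the N50 length in bp.
#' @examples
#' compute_n50(c(8, 8, 4, 3, 3, 2, 2, 2))  # 8
#' @export
compute_n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("cannot compute N50 of an empty length set")
  stopifnot(all(lengths > 0))
  srt <- sort(lengths, decreasing = TRUE)
  srt[which(cumsum(as.numeric(srt)) >= sum(as.numeric(srt)) / 2)[1L]]
}

#' Summarize an assembly's hierarchy
#'
#' Counts isogroups ("genes"), isotigs ("transcripts"), contigs ("exons")
#' and singletons, plus the derived ratios reported in standard assembly
#' tables: mean isotigs per isogroup, the fraction of isogroups containing
#' a single isotig, mean contigs per isotig, and the isotig N50 (over all
#' isotigs, or over the longest isotig per isogroup).
#'
#' @param assembly an [assembly_set()].
#' @param n50_scope `"all_isotigs"` or `"longest_per_isogroup"`.
#' @return a list of class `assembly_summary` with the raw counts and
#'   ratios, plus `report`, the same ratios rounded to table precision
#'   (one decimal; fractions as percentages).
#' @export
summarize_assembly <- function(assembly,
                               n50_scope = c("all_isotigs",
                                             "longest_per_isogroup")) {
  n50_scope <- match.arg(n50_scope)
  stopifnot(inherits(assembly, "assembly_set"))
  mem <- assembly$membership
  if (nrow(mem) == 0L) stop("empty assembly")
  iso_per_grp <- table(mem$isogroup_id)
  lens <- nchar(assembly$isotig_seqs$residues)
  names(lens) <- assembly$isotig_seqs$id
  n50_ids <- if (n50_scope == "all_isotigs") mem$isotig_id
             else longest_isotig_per_isogroup(assembly)
  out <- list(
    n_isogroups = length(iso_per_grp),
    n_isotigs = nrow(mem),
    n_contigs = length(unique(unlist(mem$contig_ids, use.names = FALSE))),
    n_singletons = nrow(assembly$singleton_seqs),
    mean_isotigs_per_isogroup = nrow(mem) / length(iso_per_grp),
    frac_single_isotig_isogroups = mean(iso_per_grp == 1L),
    mean_contigs_per_isotig = mean(lengths(mem$contig_ids)),
    isotig_n50 = compute_n50(unname(lens[n50_ids])),
    n50_scope = n50_scope)
  out$report <- list(
    mean_isotigs_per_isogroup = report_ratio(out$mean_isotigs_per_isogroup),
    frac_single_isotig_isogroups =
      report_percent(sum(iso_per_grp == 1L), length(iso_per_grp)),
    mean_contigs_per_isotig = report_ratio(out$mean_contigs_per_isotig))
  class(out) <- "assembly_summary"
  out
}

#' @export
print.assembly_summary <- function(x, ...) {
  cat("Assembly summary\n",
      "  isogroups (\"genes\"):      ", x$n_isogroups, "\n",
      "  isotigs (\"transcripts\"):  ", x$n_isotigs, "\n",
      "  contigs (\"exons\"):        ", x$n_contigs, "\n",
      "  singletons:               ", x$n_singletons, "\n",
      "  mean isotigs/isogroup:    ", x$report$mean_isotigs_per_isogroup, "\n",
      "  single-isotig isogroups:  ", x$report$frac_single_isotig_isogroups,
      "%\n",
      "  mean contigs/isotig:      ", x$report$mean_contigs_per_isotig, "\n",
      "  isotig N50 (", x$n50_scope, "): ", x$isotig_n50, " bp\n", sep = "")
  invisible(x)
}

#' Histogram of sequence lengths over fixed-width bins
#'
#' Bins are half-open, `[k*w, (k+1)*w)`, so every length lands in exactly
#' one bin and counts always sum to the number of inputs.
#'
#' @param lengths sequence lengths in bp.
#' @param bin_width bin width in bp (>= 1).
#' @return a `data.frame` with `bin_start`, `bin_end` (exclusive) and
#'   `count`, ordered by bin.
#' @export
length_histogram <- function(lengths, bin_width) {
  if (length(bin_width) != 1L || bin_width < 1) {
    stop("bin_width must be a single value >= 1")
  }
  if (length(lengths) == 0L) {
    return(data.frame(bin_start = numeric(), bin_end = numeric(),
                      count = integer()))
  }
  bin <- floor(lengths / bin_width)
  tab <- table(bin)
  starts <- as.numeric(names(tab)) * bin_width
  data.frame(bin_start = starts, bin_end = starts + bin_width,
             count = as.integer(tab))
}

#' Per-contig read coverage
#'
#' Coverage of a contig is the total bases contained in the reads used to
#' construct it, divided by the contig length (reads per bp).
#'
#' @param contig_info a `data.frame` with `length` and `read_bp` columns
#'   (one or more contigs).
#' @return numeric vector of coverages, one per row.
#' @export
contig_coverage <- function(contig_info) {
  if (any(contig_info$length <= 0)) stop("contig with non-positive length")
  zero <- contig_info$read_bp == 0
  if (any(zero)) {
    warning(sum(zero), " contig(s) have no assigned read bases; coverage 0")
  }
  contig_info$read_bp / contig_info$length
}

#' Select the longest isotig of each isogroup
#'
#' Downstream annotation statistics are reported over the longest isotig
#' per isogroup, on the assumption that isotigs within an isogroup share
#' nearly identical hits.  Length ties break to the lexicographically
#' smallest isotig id.
#'
#' @param assembly an [assembly_set()].
#' @return character vector of isotig ids, one per isogroup.
#' @export
longest_isotig_per_isogroup <- function(assembly) {
  mem <- assembly$membership
  lens <- nchar(assembly$isotig_seqs$residues)
  names(lens) <- assembly$isotig_seqs$id
  if (anyNA(lens[mem$isotig_id])) {
    stop("isotig without sequence: ",
         mem$isotig_id[is.na(lens[mem$isotig_id])][1L])
  }
  # order by isogroup, then length desc, then id asc; keep the first of each
  o <- order(mem$isogroup_id, -lens[mem$isotig_id], mem$isotig_id)
  picked <- mem[o, ][!duplicated(mem$isogroup_id[o]), ]
  sort(picked$isotig_id)
}
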