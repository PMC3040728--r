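#' Filter hits by e-value cutoff
#'
#' @param hits a hit table ([read_blast_tab()]).
#' @param cutoff maximum e-value to retain (inclusive); the survey's
#'   annotation cutoff is `1e-10`, the read-mapping cutoff `1e-4`.
#' @return the subset of rows with `evalue <= cutoff`, order preserved.
#' @export
filter_by_evalue <- function(hits, cutoff = 1e-10) {
  stopifnot(length(cutoff) == 1L, cutoff > 0)
  hits[hits$evalue <= cutoff, , drop = FALSE]
}

#' Select each query's top BLAST hit
#'
#' For every query the hit with the smallest e-value is kept; e-value ties
#' break to the largest bitscore, remaining ties to the first row in input
#' order (BLAST's own output order, making the choice reproducible).
#'
#' @param hits an e-value-filtered hit table.
#' @param cutoff the cutoff already applied, recorded as provenance in the
#'   `evalue_cutoff` attribute.
#' @return a hit table with at most one row per query, attribute
#'   `evalue_cutoff` set.
#' @export
select_top_hits <- function(hits, cutoff = NA_real_) {
  if (nrow(hits) == 0L) {
    out <- hits
  } else {
    o <- order(match(hits$query_id, unique(hits$query_id)),
               hits$evalue, -hits$bitscore, seq_len(nrow(hits)))
    h <- hits[o, , drop = FALSE]
    out <- h[!duplicated(h$query_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "evalue_cutoff") <- cutoff
  out
}

#' Classify the queries sharing one top BLAST hit
#'
#' Given the subject-axis alignment intervals of all queries whose top hit
#' is the same database subject, decide whether they look like unassembled
#' fragments of one transcript (mutually non-overlapping intervals) or like
#' distinct gene copies -- candidate paralogs -- (overlapping intervals),
#' and how many genes they represent.  The gene count is the minimum number
#' of mutually non-overlapping chains needed to cover all intervals, which
#' for intervals equals the maximum point depth of overlap.
#'
#' @param starts,ends 1-based inclusive subject coordinates, one interval
#'   per query (`starts[i] <= ends[i]`).
#' @param tolerance two intervals are called overlapping only when they
#'   share more than `tolerance` subject positions (default 0: sharing a
#'   single position counts).
#' @return a list with `classification` -- one of `"single"` (one
#'   interval), `"merged_fragments"` (several, all disjoint),
#'   `"paralogs"` (all pairwise overlapping), `"mixed"` -- and
#'   `gene_count`.
#' @examples
#' classify_shared_subject(c(1, 150), c(100, 250))  # merged_fragments, 1
#' classify_shared_subject(c(1, 50), c(100, 150))   # paralogs, 2
#' @export
classify_shared_subject <- function(starts, ends, tolerance = 0L) {
  n <- length(starts)
  stopifnot(n >= 1L, length(ends) == n, all(starts <= ends), tolerance >= 0L)
  # requiring overlap length > t is equivalent to shrinking right ends by t
  ends_t <- pmax(starts, ends - tolerance)
  depth <- max_interval_depth(starts, ends_t)
  classification <-
    if (n == 1L) "single"
    else if (depth == 1L) "merged_fragments"
    else if (depth == n) "paralogs"
    else "mixed"
  list(classification = classification, gene_count = depth)
}

# Maximum number of intervals covering any single point (sweep line).
max_interval_depth <- function(starts, ends) {
  ev <- c(starts, ends + 1L)
  delta <- rep(c(1L, -1L), each = length(starts))
  o <- order(ev, delta)  # at equal coordinate, closings (end+1) act first
  max(cumsum(delta[o]))
}

#' Collapse top hits into a unique-gene tally
#'
#' Queries sharing a top BLAST hit are collapsed: under
#' `mode = "interval_aware"` (the rule used for isotigs and contigs) each
#' shared subject contributes [classify_shared_subject()]'s gene count --
#' non-overlapping fragments of one transcript are counted once, candidate
#' paralogs are all retained; under `mode = "one_per_subject"` (the rule
#' used for singletons, where identical unassembled reads are frequent)
#' each subject is counted exactly once regardless of overlap.
#'
#' @param top a top-hit table from [select_top_hits()].
#' @param mode counting rule, `"interval_aware"` or `"one_per_subject"`.
#' @param tolerance overlap tolerance forwarded to
#'   [classify_shared_subject()].
#' @return a list of class `gene_tally`: `per_subject` data frame
#'   (`subject_id`, `n_queries`, `classification`, `gene_count`, plus
#'   list columns `query_ids`, `starts`, `ends`),
#'   `total_unique_genes`, and `n_merged_away`
#'   (queries minus unique genes).
#' @export
unique_gene_tally <- function(top, mode = c("interval_aware",
                                            "one_per_subject"),
                              tolerance = 0L) {
  mode <- match.arg(mode)
  if (nrow(top) == 0L) {
    per <- data.frame(subject_id = character(), n_queries = integer(),
                      classification = character(), gene_count = integer(),
                      stringsAsFactors = FALSE)
    return(structure(list(per_subject = per, total_unique_genes = 0L,
                          n_merged_away = 0L, mode = mode),
                     class = "gene_tally"))
  }
  split_idx <- split(seq_len(nrow(top)), top$subject_id)
  rows <- lapply(names(split_idx), function(sid) {
    i <- split_idx[[sid]]
    if (mode == "one_per_subject") {
      cls <- if (length(i) == 1L) "single" else "merged_fragments"
      cnt <- 1L
    } else {
      cl <- classify_shared_subject(top$s_start[i], top$s_end[i], tolerance)
      cls <- cl$classification
      cnt <- cl$gene_count
    }
    data.frame(subject_id = sid, n_queries = length(i),
               classification = cls, gene_count = cnt,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  per$query_ids <- lapply(split_idx, function(i) top$query_id[i])
  per$starts <- lapply(split_idx, function(i) top$s_start[i])
  per$ends <- lapply(split_idx, function(i) top$s_end[i])
  structure(list(per_subject = per,
                 total_unique_genes = sum(per$gene_count),
                 n_merged_away = nrow(top) - sum(per$gene_count),
                 mode = mode),
            class = "gene_tally")
}

#' @export
print.gene_tally <- function(x, ...) {
  cat("Unique-gene tally (", x$mode, ")\n",
      "  queries:        ", sum(x$per_subject$n_queries), "\n",
      "  subjects:       ", nrow(x$per_subject), "\n",
      "  unique genes:   ", x$total_unique_genes, "\n",
      "  merged away:    ", x$n_merged_away, "\n", sep = "")
  cls <- table(x$per_subject$classification)
  for (k in names(cls)) cat("    ", k, ": ", cls[[k]], "\n", sep = "")
  invisible(x)
}

#' Combined unique-gene count over assembled sequences and singletons
#'
#' The mixed counting rule used for discovery curves: assembled queries
#' (longest isotig per isogroup, plus secondary contigs) are collapsed
#' interval-aware, singletons are counted at most one per subject, and a
#' singleton-only subject contributes one gene.  A subject already hit by
#' an assembled sequence gains nothing from its singletons (the
#' conservative reading: such reads are presumed fragments of the
#' already-counted transcript).
#'
#' @param top_assembled top-hit table for assembled sequences.
#' @param top_singletons top-hit table for singleton reads.
#' @param tolerance overlap tolerance for the interval-aware part.
#' @return a list with `total_unique_genes`, `assembled_tally` and
#'   `singleton_only_subjects`.
#' @export
combined_gene_tally <- function(top_assembled, top_singletons,
                                tolerance = 0L) {
  at <- unique_gene_tally(top_assembled, "interval_aware", tolerance)
  extra <- setdiff(unique(top_singletons$subject_id),
                   at$per_subject$subject_id)
  list(total_unique_genes = at$total_unique_genes + length(extra),
       assembled_tally = at,
       singleton_only_subjects = extra)
}

#' Taxon breakdown of top BLAST hits
#'
#' @param top a top-hit table.
#' @param taxon_map named character vector mapping subject ids to taxa;
#'   subjects missing from the map fall into `"unknown"`.
#' @param min_count taxa with fewer hits than this are pooled into
#'   `"other"`.
#' @return a `data.frame` of `taxon` and `count`, descending by count.
#' @export
species_breakdown <- function(top, taxon_map, min_count = 1L) {
  if (nrow(top) == 0L) {
    return(data.frame(taxon = character(), count = integer()))
  }
  taxa <- unname(taxon_map[top$subject_id])
  taxa[is.na(taxa)] <- "unknown"
  tab <- table(taxa)
  small <- tab < min_count
  if (any(small)) {
    tab <- c(tab[!small], other = sum(tab[small]))
  }
  out <- data.frame(taxon = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$taxon), , drop = FALSE]
}
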