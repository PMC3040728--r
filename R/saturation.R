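#' Combine two read samples in seeded random order
#'
#' Reads from two libraries are concatenated and shuffled with a seeded
#' Fisher-Yates permutation (R's Mersenne-Twister stream), emulating the
#' "combined in random order, sampled without replacement" design of
#' sub-assembly construction.  The same seed always yields the same order.
#'
#' @param reads_a,reads_b read tables (any data frame with one row per
#'   read).
#' @param seed integer seed.
#' @return a single data frame, a permutation of the row-bound input.
#' @export
interleave_samples <- function(reads_a, reads_b, seed) {
  combined <- rbind(reads_a, reads_b)
  if (nrow(combined) == 0L) return(combined)
  perm <- withr::with_seed(seed, sample.int(nrow(combined)))
  out <- combined[perm, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subsample reads without replacement, with nested subsets
#'
#' Takes the first `n` elements of the seeded shuffle of `reads`, so for a
#' fixed seed the sample at a smaller `n` is always a subset of the sample
#' at a larger `n` (nested subsets make discovery counts monotone by
#' construction).
#'
#' @param reads a read table.
#' @param n number of reads to keep (`0 <= n <= nrow(reads)`).
#' @param seed integer seed.
#' @return the sampled read table.
#' @export
subsample_reads <- function(reads, n, seed) {
  if (n > nrow(reads)) {
    stop("requested ", n, " reads but only ", nrow(reads), " available")
  }
  if (n < 0L) stop("n must be non-negative")
  perm <- withr::with_seed(seed, sample.int(nrow(reads)))
  out <- reads[perm[seq_len(n)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-discovery saturation curve
#'
#' For each subsample size: draw a nested subsample of the shuffled reads,
#' assemble it through the supplied assembler adapter, emulate or collect
#' BLAST hits, and count unique genes with the mixed rule (longest isotig
#' per isogroup, interval-aware; singletons, one per subject) together with
#' the N50 over the longest isotigs per isogroup.  A plateau in unique
#' genes with a still-rising N50 indicates that further sequencing
#' lengthens known transcripts rather than finding new genes.
#'
#' @param reads a read table (e.g. from [interleave_samples()]).
#' @param sizes ascending subsample sizes.
#' @param assembler an adapter: `function(reads)` returning
#'   `list(assembly = <assembly_set>, singleton_reads = <read table>)`,
#'   deterministic for a fixed input order (see [emulated_assembler()]).
#' @param blast_fn `function(assembly, singleton_reads)` returning a hit
#'   table for the assembled sequences and singletons (see
#'   [emulated_blaster()]).
#' @param evalue_cutoff annotation cutoff applied before top-hit selection.
#' @param seed integer seed driving the shuffle.
#' @param independent if `TRUE`, each size is drawn with an independent
#'   shuffle (seed offset by the size index) instead of nested prefixes,
#'   mimicking independently drawn sub-assemblies.
#' @return a `data.frame` with one row per size: `n_reads`,
#'   `unique_hits`, `n50`.
#' @export
discovery_curve <- function(reads, sizes, assembler, blast_fn,
                            evalue_cutoff = 1e-10, seed = 1L,
                            independent = FALSE) {
  if (is.unsorted(sizes, strictly = TRUE)) {
    stop("sizes must be strictly ascending")
  }
  rows <- lapply(seq_along(sizes), function(k) {
    n <- sizes[k]
    sub <- if (independent) {
      subsample_reads(reads, n, seed + k)
    } else {
      subsample_reads(reads, n, seed)
    }
    res <- tryCatch(assembler(sub), error = function(e) {
      stop("assembler adapter failed at subsample size ", n, ": ",
           conditionMessage(e))
    })
    point <- curve_point(res$assembly, res$singleton_reads, blast_fn,
                         evalue_cutoff)
    data.frame(n_reads = n, unique_hits = point$unique_hits,
               n50 = point$n50)
  })
  do.call(rbind, rows)
}

curve_point <- function(assembly, singleton_reads, blast_fn, evalue_cutoff) {
  hits <- blast_fn(assembly, singleton_reads)
  hits <- filter_by_evalue(hits, evalue_cutoff)
  if (nrow(assembly$membership)) {
    keep <- longest_isotig_per_isogroup(assembly)
    lens <- nchar(assembly$isotig_seqs$residues)
    names(lens) <- assembly$isotig_seqs$id
    n50 <- compute_n50(unname(lens[keep]))
  } else {
    keep <- character()
    n50 <- NA_integer_
  }
  singleton_ids <- if (nrow(singleton_reads)) singleton_reads$id
                   else character()
  top_asm <- select_top_hits(hits[hits$query_id %in% keep, , drop = FALSE],
                             evalue_cutoff)
  top_sng <- select_top_hits(
    hits[hits$query_id %in% singleton_ids, , drop = FALSE], evalue_cutoff)
  tally <- combined_gene_tally(top_asm, top_sng)
  list(unique_hits = tally$total_unique_genes, n50 = n50)
}

#' Locate the discovery plateau of a curve
#'
#' The smallest read count at which the forward finite-difference slope of
#' unique hits per read falls below a threshold; `NA` if the curve never
#' flattens to that degree.
#'
#' @param curve a `data.frame` from [discovery_curve()] (`n_reads`,
#'   `unique_hits`).
#' @param slope_threshold genes per read.
#' @return the plateau `n_reads`, or `NA` if never reached.
#' @export
plateau_estimate <- function(curve, slope_threshold) {
  if (nrow(curve) < 2L) stop("plateau estimation needs at least 2 points")
  if (is.unsorted(curve$n_reads, strictly = TRUE)) {
    stop("curve must be sorted by strictly increasing n_reads")
  }
  slope <- diff(curve$unique_hits) / diff(curve$n_reads)
  i <- which(slope < slope_threshold)
  if (length(i) == 0L) NA_real_ else curve$n_reads[i[1L]]
}
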