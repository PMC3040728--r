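#' Equalize two read sets to the same base-pair total
#'
#' To remove library-size bias when comparing a normalized and a
#' non-normalized sample, the larger set (by total bases) is truncated at a
#' read boundary to the largest prefix whose base total does not exceed the
#' smaller set's total; the smaller set is kept whole.
#'
#' @param reads_a,reads_b read tables with a `length` column (bp), or with
#'   a `residues` column from which lengths are taken.
#' @return a list with `reads_a`, `reads_b` (possibly truncated),
#'   `bp_a`, `bp_b` (base totals after equalization), and `bp_target`.
#' @export
equalize_bases <- function(reads_a, reads_b) {
  la <- read_lengths(reads_a)
  lb <- read_lengths(reads_b)
  if (length(la) == 0L || length(lb) == 0L) stop("both read sets must be non-empty")
  ta <- sum(as.numeric(la)); tb <- sum(as.numeric(lb))
  target <- min(ta, tb)
  trim <- function(reads, lens) {
    keep <- which(cumsum(as.numeric(lens)) <= target)
    if (length(keep) == 0L) {
      warning("no read prefix fits within ", target,
              " bp; returning an empty set")
      return(reads[0L, , drop = FALSE])
    }
    reads[seq_len(max(keep)), , drop = FALSE]
  }
  if (ta > tb) reads_a <- trim(reads_a, la)
  if (tb > ta) reads_b <- trim(reads_b, lb)
  list(reads_a = reads_a, reads_b = reads_b,
       bp_a = sum(as.numeric(read_lengths(reads_a))),
       bp_b = sum(as.numeric(read_lengths(reads_b))),
       bp_target = target)
}

read_lengths <- function(reads) {
  if ("length" %in% names(reads)) reads$length
  else if ("residues" %in% names(reads)) nchar(reads$residues)
  else stop("read table needs a 'length' or 'residues' column")
}

#' Per-sample, per-contig read counts from read-vs-assembly hits
#'
#' Maps raw reads against the assembled transcriptome (BLASTN-style hits),
#' keeps each read's top hit passing the e-value cutoff, and counts the
#' reads landing on every contig, split by sample label.  The per-sample
#' maximum reads-per-contig is the statistic that drops under successful
#' cDNA normalization (normalization preferentially removes reads from the
#' most abundant transcripts).
#'
#' @param read_hits hit table of reads vs the assembly.
#' @param sample_map named character vector: read id to sample label
#'   (e.g. `"N"`, `"NN"`).
#' @param evalue_cutoff mapping cutoff (the survey used `1e-4` for read
#'   mapping, versus `1e-10` for annotation).
#' @return a list with `counts` (named list per sample: named integer
#'   vector contig to count) and `max_reads_per_contig` (named numeric
#'   per sample).
#' @export
per_contig_read_counts <- function(read_hits, sample_map,
                                   evalue_cutoff = 1e-4) {
  hits <- filter_by_evalue(read_hits, evalue_cutoff)
  top <- select_top_hits(hits, evalue_cutoff)
  if (nrow(top)) {
    missing <- setdiff(top$query_id, names(sample_map))
    if (length(missing)) {
      stop("read '", missing[1L], "' is absent from the sample map")
    }
  }
  samples <- sort(unique(unname(sample_map)))
  counts <- lapply(samples, function(s) {
    q <- top[sample_map[top$query_id] == s, , drop = FALSE]
    tab <- table(q$subject_id)
    stats::setNames(as.integer(tab), names(tab))
  })
  names(counts) <- samples
  list(counts = counts,
       max_reads_per_contig = vapply(counts, function(x)
         if (length(x)) max(x) else 0L, numeric(1L)))
}

#' Partition hit ids into sample-exclusive and shared sets
#'
#' @param counts_a,counts_b named count vectors (or plain id vectors) of
#'   contigs/genes hit by each sample.
#' @return a list of three disjoint id sets: `only_a`, `only_b`, `both`,
#'   partitioning the union.
#' @export
exclusive_hit_sets <- function(counts_a, counts_b) {
  ids_a <- if (is.null(names(counts_a))) as.character(counts_a)
           else names(counts_a)
  ids_b <- if (is.null(names(counts_b))) as.character(counts_b)
           else names(counts_b)
  list(only_a = setdiff(ids_a, ids_b),
       only_b = setdiff(ids_b, ids_a),
       both = intersect(ids_a, ids_b))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric two-sided p-value for the table
#' `rbind(c(a, b), c(c, d))` with fixed margins.  The default convention
#' sums the probabilities of all tables whose point probability does not
#' exceed that of the observed table (the convention of common exact-test
#' implementations, within a small relative tolerance); the alternative
#' doubling convention takes twice the smaller one-sided tail, capped at 1.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param convention `"minlike"` (point-probability) or `"doubling"`.
#' @return the two-sided p-value.
#' @examples
#' fisher_exact_2x2(3, 0, 0, 3)  # 0.1
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             convention = c("minlike", "doubling")) {
  convention <- match.arg(convention)
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == floor(cells)))
  if (sum(cells) == 0) stop("all margins are zero")
  m <- a + b          # row-1 margin
  n <- c + d          # row-2 margin
  k <- a + c          # column-1 margin
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- probs[support == a]
  if (convention == "minlike") {
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  } else {
    lower <- sum(probs[support <= a])
    upper <- sum(probs[support >= a])
    p <- min(1, 2 * min(lower, upper))
  }
  min(1, p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, order-preserving with monotone enforcement
#' and clipped at 1 (delegates to [stats::p.adjust()] with
#' `method = "BH"` after validation).
#'
#' @param pvalues probabilities in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Compare GO-term distributions of two gene sets
#'
#' Each query contributes each of its ancestor-closed GO terms at most
#' once.  Per term, membership counts in set A and set B form a 2x2 table
#' against the set sizes; the two-sided Fisher p-value and a
#' Benjamini-Hochberg q-value across all tested terms identify over- and
#' under-represented terms, and per-set percentage distributions summarize
#' the overall profiles.  Queries without annotation still count in the
#' set sizes.
#'
#' @param set_a,set_b character vectors of query ids (typically the
#'   sample-exclusive hit sets from [exclusive_hit_sets()]).
#' @param annotation a `go_annotation` ([read_go_mapping()]).
#' @param convention Fisher two-sided convention (see
#'   [fisher_exact_2x2()]).
#' @return a `data.frame` with one row per term: `term`, `label`, `a`,
#'   `n_test`, `b`, `n_ref`, `pct_a`, `pct_b`, `p`, `q`, sorted by `p`.
#' @export
go_term_comparison <- function(set_a, set_b, annotation,
                               convention = "minlike") {
  stopifnot(inherits(annotation, "go_annotation"))
  if (length(set_a) == 0L && length(set_b) == 0L) {
    stop("both query sets are empty")
  }
  n_a <- length(set_a)
  n_b <- length(set_b)
  terms_a <- annotation$query_terms[intersect(set_a,
                                              names(annotation$query_terms))]
  terms_b <- annotation$query_terms[intersect(set_b,
                                              names(annotation$query_terms))]
  count_terms <- function(lst) {
    if (length(lst) == 0L) return(integer())
    tab <- table(unlist(lst, use.names = FALSE))
    stats::setNames(as.integer(tab), names(tab))
  }
  ca <- count_terms(terms_a)
  cb <- count_terms(terms_b)
  terms <- sort(union(names(ca), names(cb)))
  if (length(terms) == 0L) {
    return(data.frame(term = character(), label = character(),
                      a = integer(), n_test = integer(), b = integer(),
                      n_ref = integer(), pct_a = numeric(),
                      pct_b = numeric(), p = numeric(), q = numeric()))
  }
  a <- ifelse(terms %in% names(ca), ca[terms], 0L)
  b <- ifelse(terms %in% names(cb), cb[terms], 0L)
  p <- vapply(seq_along(terms), function(i) {
    fisher_exact_2x2(a[i], n_a - a[i], b[i], n_b - b[i],
                     convention = convention)
  }, numeric(1L))
  labels <- if (is.null(annotation$labels)) rep(NA_character_, length(terms))
            else unname(annotation$labels[terms])
  out <- data.frame(term = terms, label = labels,
                    a = as.integer(a), n_test = n_a,
                    b = as.integer(b), n_ref = n_b,
                    pct_a = 100 * a / n_a, pct_b = 100 * b / n_b,
                    p = p, q = bh_fdr(p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
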