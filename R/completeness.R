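#' Ortholog hit ratio of top hits
#'
#' The ortholog hit ratio (OHR) compares the length of the newly assembled
#' sequence that obtains a BLAST hit with the full length of its top
#' database hit.  A ratio of 1 implies a transcript assembled to its true
#' full length; values over 1 suggest insertions in the query relative to
#' the subject.  For protein subjects (BLASTX-style searches) the aligned
#' query span in nucleotides is converted to codons before dividing by the
#' subject length in residues; for nucleotide subjects the spans are
#' compared directly.
#'
#' @param hits a top-hit table whose rows carry `subject_len`.
#' @param subject_kind `"protein"` or `"nucleotide"`.
#' @return a `data.frame` with `query_id`, `subject_id`,
#'   `aligned_query_span` (nt), `subject_len`, `ratio`, and
#'   `possible_insertion` (`ratio > 1`).
#' @examples
#' h <- data.frame(query_id = "q", subject_id = "s",
#'                 q_start = 1, q_end = 300, subject_len = 100)
#' ortholog_hit_ratio(h, "protein")$ratio  # 1
#' @export
ortholog_hit_ratio <- function(hits, subject_kind = c("protein",
                                                      "nucleotide")) {
  subject_kind <- match.arg(subject_kind)
  if (nrow(hits) == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      aligned_query_span = integer(),
                      subject_len = integer(), subject_kind = character(),
                      ratio = numeric(), possible_insertion = logical(),
                      stringsAsFactors = FALSE))
  }
  if (anyNA(hits$subject_len)) {
    stop("subject_len missing for query '",
         hits$query_id[is.na(hits$subject_len)][1L],
         "': read hits with expect_subject_len = TRUE (13-column slen ",
         "output) or join a subject-lengths table first")
  }
  stopifnot(all(hits$subject_len >= 1))
  span <- hits$q_end - hits$q_start + 1L
  ratio <- if (subject_kind == "protein") (span / 3) / hits$subject_len
           else span / hits$subject_len
  data.frame(query_id = hits$query_id, subject_id = hits$subject_id,
             aligned_query_span = span, subject_len = hits$subject_len,
             subject_kind = subject_kind, ratio = ratio,
             possible_insertion = ratio > 1,
             stringsAsFactors = FALSE)
}

#' Distribution of ortholog hit ratios
#'
#' Histogram over half-open bins plus the fractions of records whose ratio
#' strictly exceeds the completeness thresholds (by default 0.5 and 0.8,
#' the landmarks of the survey's completeness figure).
#'
#' @param records the output of [ortholog_hit_ratio()].
#' @param bin_width bin width on the ratio axis.
#' @param thresholds thresholds for the strict-exceedance fractions.
#' @return a list with `histogram` (`bin_start`, `bin_end`, `count`),
#'   `fractions` (named, raw), and `report` (the same fractions as
#'   one-decimal percentages).
#' @export
ohr_distribution <- function(records, bin_width = 0.1,
                             thresholds = c(0.5, 0.8)) {
  if (nrow(records) == 0L) stop("no OHR records")
  r <- records$ratio
  bin <- floor(r / bin_width)
  tab <- table(bin)
  starts <- as.numeric(names(tab)) * bin_width
  frac <- vapply(thresholds, function(t) mean(r > t), numeric(1L))
  names(frac) <- paste0("gt_", thresholds)
  list(histogram = data.frame(bin_start = starts,
                              bin_end = starts + bin_width,
                              count = as.integer(tab)),
       fractions = frac,
       report = vapply(thresholds, function(t)
         report_percent(sum(r > t), length(r)), numeric(1L)))
}

#' Net sequence gain of transcriptome data over a known reference accession
#'
#' Given plus-strand alignments of one or more assembled transcripts to a
#' known reference sequence, computes how far the transcriptome data extend
#' beyond the reference's 5' and 3' ends (overhangs projected from
#' transcript coordinates), and the merged span of the reference covered by
#' the alignments.  Reference-coordinate gaps between alignment blocks are
#' reported as separate blocks: the known reference itself bridges them,
#' confirming the transcripts as fragments of a single gene.
#'
#' @param reference_len length of the reference accession in bp.
#' @param alignments `data.frame` with columns `ref_start`, `ref_end`,
#'   `tx_start`, `tx_end`, `tx_len` (one row per transcript alignment;
#'   spans of equal length on both axes, plus strand).
#' @return a list with `gain5`, `gain3` (bp, maxima over transcripts),
#'   `total_gain`, and `merged_ref_span` (`data.frame` of covered
#'   blocks).
#' @examples
#' aln <- data.frame(ref_start = 1, ref_end = 1000,
#'                   tx_start = 101, tx_end = 1100, tx_len = 1400)
#' extension_gain(1000, aln)  # gain5 100, gain3 300
#' @export
extension_gain <- function(reference_len, alignments) {
  a <- alignments
  stopifnot(nrow(a) >= 1L, all(a$ref_start <= a$ref_end),
            all(a$tx_start <= a$tx_end), all(a$tx_end <= a$tx_len))
  if (any(a$ref_end - a$ref_start != a$tx_end - a$tx_start)) {
    stop("alignment spans differ in length between axes; ",
         "pre-orient and ungap alignments to the plus strand first")
  }
  gain5 <- max(pmax(0L, (a$tx_start - 1L) - (a$ref_start - 1L)))
  gain3 <- max(pmax(0L, (a$tx_len - a$tx_end) - (reference_len - a$ref_end)))
  merged <- IRanges::reduce(IRanges::IRanges(a$ref_start, a$ref_end))
  list(gain5 = gain5, gain3 = gain3, total_gain = gain5 + gain3,
       merged_ref_span = data.frame(start = IRanges::start(merged),
                                    end = IRanges::end(merged)))
}
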