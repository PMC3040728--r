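#' Find isogroups predicting a single-cassette splice difference
#'
#' Scans the assembly hierarchy for isogroups with exactly two isotigs
#' whose contig paths differ by the presence/absence of a single contig --
#' the pattern of a skipped-exon isoform pair that is directly testable by
#' RT-PCR: primers flanking the differing contig should amplify two bands
#' whose sizes differ by that contig's length.
#'
#' @param assembly an [assembly_set()] whose `contig_info` carries contig
#'   lengths.
#' @return a `data.frame` with one row per candidate pair: `isogroup_id`,
#'   `isotig_long`, `isotig_short`, `differing_contig_id`,
#'   `size_difference` (bp; `NA` when the contig length is unknown).
#' @export
find_isoform_pairs <- function(assembly) {
  mem <- assembly$membership
  clen <- stats::setNames(assembly$contig_info$length,
                          assembly$contig_info$contig_id)
  rows <- lapply(split(seq_len(nrow(mem)), mem$isogroup_id), function(i) {
    if (length(i) != 2L) return(NULL)
    c1 <- mem$contig_ids[[i[1L]]]
    c2 <- mem$contig_ids[[i[2L]]]
    if (abs(length(c1) - length(c2)) != 1L) return(NULL)
    long <- if (length(c1) > length(c2)) 1L else 2L
    extra <- setdiff(mem$contig_ids[[i[long]]], mem$contig_ids[[i[3L - long]]])
    # the shorter path must be the longer one minus exactly one contig
    if (length(extra) != 1L ||
        !all(mem$contig_ids[[i[3L - long]]] %in% mem$contig_ids[[i[long]]])) {
      return(NULL)
    }
    data.frame(isogroup_id = mem$isogroup_id[i[1L]],
               isotig_long = mem$isotig_id[i[long]],
               isotig_short = mem$isotig_id[i[3L - long]],
               differing_contig_id = extra,
               size_difference = if (extra %in% names(clen))
                 unname(clen[extra]) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(isogroup_id = character(), isotig_long = character(),
                      isotig_short = character(),
                      differing_contig_id = character(),
                      size_difference = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[order(out$isogroup_id), , drop = FALSE]
}

#' Predict RT-PCR amplicon sizes on template sequences
#'
#' Exact primer matching: the forward primer is matched on the given
#' strand, the reverse primer as its reverse complement.  Every
#' forward-start/reverse-end combination with the forward site beginning
#' at or before the reverse site yields a product of length
#' `reverse_end - forward_start + 1`; templates where either primer is
#' absent yield no product.
#'
#' @param templates a sequence table ([read_fasta()] layout) of candidate
#'   isotigs.
#' @param forward,reverse primer sequences (plain `ACGT`, length >= 10;
#'   degenerate bases are rejected since matching is exact).
#' @return a `data.frame` with `template_id`, `f_start`, `r_end`,
#'   `product_size` (bp), one row per product.
#' @export
predict_amplicons <- function(templates, forward, reverse) {
  check_primer(forward, "forward")
  check_primer(reverse, "reverse")
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(reverse)))
  rows <- lapply(seq_len(nrow(templates)), function(i) {
    seq <- toupper(templates$residues[i])
    f_starts <- match_positions(seq, toupper(forward))
    r_starts <- match_positions(seq, rc)
    if (length(f_starts) == 0L || length(r_starts) == 0L) return(NULL)
    combos <- expand.grid(f_start = f_starts, r_start = r_starts)
    combos <- combos[combos$f_start <= combos$r_start, , drop = FALSE]
    if (nrow(combos) == 0L) return(NULL)
    r_end <- combos$r_start + nchar(rc) - 1L
    data.frame(template_id = templates$id[i], f_start = combos$f_start,
               r_end = r_end, product_size = r_end - combos$f_start + 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(template_id = character(), f_start = integer(),
                      r_end = integer(), product_size = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

check_primer <- function(primer, what) {
  if (nchar(primer) < 10L) stop(what, " primer shorter than 10 nt")
  if (!grepl("^[ACGTacgt]+$", primer)) {
    stop(what, " primer contains degenerate or non-ACGT bases; ",
         "exact matching only")
  }
  invisible(TRUE)
}

match_positions <- function(seq, pattern) {
  hits <- gregexpr(pattern, seq, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) integer() else as.integer(hits)
}

#' Score predicted against observed band sizes
#'
#' Each predicted band is greedily matched (smallest predicted first) to
#' the nearest unmatched observed band within a relative tolerance
#' motivated by agarose-gel resolution.  The case status distinguishes
#' full support, full support with unpredicted extra bands, partial
#' support, and no support.
#'
#' @param predicted,observed positive band sizes in bp.
#' @param rel_tolerance relative size tolerance for a match (default 10%).
#' @return a list with `status` (one of `"all_predicted_seen"`,
#'   `"predicted_seen_plus_extras"`, `"partial"`, `"unsupported"`),
#'   `n_matched`, and `extras` (unmatched observed sizes).
#' @export
compare_bands <- function(predicted, observed, rel_tolerance = 0.1) {
  stopifnot(all(predicted > 0), all(observed >= 0))
  matched_obs <- rep(FALSE, length(observed))
  n_matched <- 0L
  for (p in sort(predicted)) {
    cand <- which(!matched_obs & abs(observed - p) <= rel_tolerance * p)
    if (length(cand)) {
      best <- cand[which.min(abs(observed[cand] - p))]
      matched_obs[best] <- TRUE
      n_matched <- n_matched + 1L
    }
  }
  status <- if (n_matched == length(predicted)) {
    if (any(!matched_obs)) "predicted_seen_plus_extras"
    else "all_predicted_seen"
  } else if (n_matched >= 1L) "partial" else "unsupported"
  list(status = status, n_matched = n_matched,
       extras = observed[!matched_obs])
}

#' Summarize band comparisons over a case table
#'
#' @param cases a list of cases, each a list with elements `predicted` and
#'   `observed` (band-size vectors), optionally named by case id.
#' @param rel_tolerance forwarded to [compare_bands()].
#' @return a list with `per_case` (`data.frame` of case, status, counts),
#'   `frac_all_predicted_seen`, `frac_with_extras`, and
#'   `single_product_rate` -- the fraction of cases where multiple bands
#'   were predicted but a single product was observed (the isoform
#'   false-positive rate), raw and at report precision.
#' @export
score_band_cases <- function(cases, rel_tolerance = 0.1) {
  ids <- if (is.null(names(cases))) as.character(seq_along(cases))
         else names(cases)
  per <- do.call(rbind, lapply(seq_along(cases), function(i) {
    cmp <- compare_bands(cases[[i]]$predicted, cases[[i]]$observed,
                         rel_tolerance)
    data.frame(case = ids[i], n_predicted = length(cases[[i]]$predicted),
               n_observed = length(cases[[i]]$observed),
               status = cmp$status, n_matched = cmp$n_matched,
               stringsAsFactors = FALSE)
  }))
  supported <- per$status %in% c("all_predicted_seen",
                                 "predicted_seen_plus_extras")
  single_product <- per$n_predicted >= 2L & per$n_observed == 1L
  list(per_case = per,
       frac_all_predicted_seen = mean(supported),
       frac_with_extras = mean(per$status == "predicted_seen_plus_extras"),
       single_product_rate = mean(single_product),
       report = c(
         pct_all_predicted_seen = report_percent(sum(supported), nrow(per)),
         pct_with_extras = report_percent(
           sum(per$status == "predicted_seen_plus_extras"), nrow(per)),
         pct_single_product = report_percent(sum(single_product), nrow(per))))
}
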