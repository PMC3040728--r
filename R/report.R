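#' Table-precision rounding helpers
#'
#' Survey reports print percentages and ratios at one-decimal precision.
#' These helpers are the single rounding path used by every report in the
#' package, so printed values are reproducible from raw numerators and
#' denominators.  Rounding is round-half-up at the requested number of
#' decimals (the convention of the printed tables), not IEEE
#' round-half-even.
#'
#' @param numerator,denominator counts.
#' @param digits decimals to keep.
#' @return `report_percent`: `100 * numerator / denominator` rounded;
#'   `report_ratio`: the plain ratio rounded.
#' @examples
#' report_percent(14562, 16617)  # 87.6
#' report_ratio(21097 / 16617)   # 1.3
#' @export
report_percent <- function(numerator, denominator, digits = 1L) {
  round_half_up(100 * numerator / denominator, digits)
}

#' @rdname report_percent
#' @param x a raw ratio.
#' @export
report_ratio <- function(x, digits = 1L) {
  round_half_up(x, digits)
}

round_half_up <- function(x, digits) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Published counts from the milkweed bug transcriptome survey
#'
#' Loads the printed accounting of a 454 pyrosequencing survey of the
#' *Oncopeltus fasciatus* ovarian and embryonic transcriptome (read counts
#' per sequencing run, assembly hierarchy sizes, annotation tallies,
#' ortholog-hit-ratio counts and GO enrichment cell counts), shipped as a
#' plain-text key/value table.  These are the worked-example inputs for the
#' package's accounting and report-rounding checks.
#'
#' @return a named numeric vector of counts.
#' @examples
#' cts <- survey_reported_counts()
#' report_percent(cts[["reads_used"]], cts[["total_reads"]])  # 97.8
#' @export
survey_reported_counts <- function() {
  path <- system.file("extdata", "oncopeltus_counts.tsv",
                      package = "transurvey", mustWork = TRUE)
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab$value), tab$key)
}
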