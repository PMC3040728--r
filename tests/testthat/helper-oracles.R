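# Independent brute-force oracles used to freeze expected values.

# Minimum number of groups of mutually non-overlapping intervals needed to
# cover all intervals: exhaustive backtracking over group assignments
# (independent of the sweep-line max-depth route in the package).
brute_min_chains <- function(starts, ends) {
  n <- length(starts)
  if (n == 0L) return(0L)
  overlap <- outer(seq_len(n), seq_len(n), function(i, j) {
    pmax(starts[i], starts[j]) <= pmin(ends[i], ends[j])
  })
  best <- n
  assign <- integer(n)
  rec <- function(i, k) {
    if (k >= best && i <= n) return(invisible())
    if (i > n) {
      best <<- min(best, k)
      return(invisible())
    }
    for (g in seq_len(k)) {
      members <- which(assign[seq_len(i - 1L)] == g)
      if (!any(overlap[i, members])) {
        assign[i] <<- g
        rec(i + 1L, k)
        assign[i] <<- 0L
      }
    }
    assign[i] <<- k + 1L
    rec(i + 1L, k + 1L)
    assign[i] <<- 0L
    invisible()
  }
  rec(1L, 0L)
  best
}

# Two-sided Fisher p by direct combinatorial enumeration (lchoose), the
# point-probability convention.
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0L, k - n):min(k, m)
  p <- exp(lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k))
  min(1, sum(p[p <= p[support == a] * (1 + 1e-7)]))
}

# N50 as the largest length L present in the set such that sequences of
# length >= L still hold at least half of all bases.
n50_oracle <- function(lengths) {
  total <- sum(as.numeric(lengths))
  cand <- sort(unique(lengths), decreasing = TRUE)
  keep <- vapply(cand, function(L) {
    sum(as.numeric(lengths[lengths >= L])) >= total / 2
  }, logical(1L))
  max(cand[keep])
}

# A tiny hand-built assembly: two isogroups, one an isoform pair whose
# paths differ by contig c2.
toy_assembly <- function() {
  mem <- data.frame(isotig_id = c("i1", "i2", "i3"),
                    isogroup_id = c("g1", "g1", "g2"),
                    stringsAsFactors = FALSE)
  mem$contig_ids <- list(c("c1", "c2", "c3"), c("c1", "c3"), "c4")
  seqs <- data.frame(
    id = c("i1", "i2", "i3"),
    description = "",
    residues = c(strrep("ACGT", 75), strrep("ACGT", 50), strrep("ACGT", 25)),
    role = "isotig", stringsAsFactors = FALSE)
  info <- data.frame(contig_id = c("c1", "c2", "c3", "c4"),
                     length = c(100L, 100L, 100L, 100L),
                     n_reads = c(10L, 5L, 8L, 2L),
                     read_bp = c(2320L, 1200L, 1900L, 500L),
                     stringsAsFactors = FALSE)
  assembly_set(mem, seqs, info)
}

# Build a minimal hit table with given per-row fields.
toy_hits <- function(query_id, subject_id, evalue, bitscore = 100,
                     s_start = 1L, s_end = 100L, q_start = 1L,
                     q_end = 300L, subject_len = NA_integer_) {
  data.frame(query_id = query_id, subject_id = subject_id,
             pct_identity = 95, aln_len = 100L, mismatches = 5L,
             gap_opens = 0L, q_start = q_start, q_end = q_end,
             s_start = s_start, s_end = s_end, evalue = evalue,
             bitscore = bitscore, subject_len = subject_len,
             q_strand = "plus", s_strand = "plus",
             stringsAsFactors = FALSE)
}
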