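#' Simulation configuration
#'
#' Free parameters of the synthetic transcriptome generator.  The defaults
#' describe a desk-scale 454-style survey: a few hundred genes with a wide
#' log-normal abundance range, Titanium-like read lengths (mean 300 bp,
#' truncated at the 50 bp assembler cutoff), a skipped-cassette isoform
#' rate, and a handful of recently duplicated paralog pairs.
#'
#' @param n_genes total number of genes (paralog-pair members included).
#' @param n_paralog_pairs number of paralog pairs; each pair is an
#'   original gene plus a copy mutated at ~10% of codons, so the two
#'   encode proteins of >= 80% identity and share a best database hit
#'   (`2 * n_paralog_pairs <= n_genes`).
#' @param isoform_probability probability that a gene carries a second,
#'   shorter isoform lacking its cassette exon.
#' @param exons_per_transcript integer range (min, max) of coding exons.
#' @param exon_length bp range (min, max) of a coding exon.
#' @param utr_length bp range of each untranslated end.
#' @param cassette_length bp length of the skippable cassette exon,
#'   placed between the coding region and the 3' UTR so both isoforms
#'   encode the same protein and their lengths differ by exactly this
#'   amount.
#' @param abundance_meanlog,abundance_sdlog log-normal parameters of
#'   per-transcript relative abundance.
#' @param read_length_mean,read_length_sd normal read-length distribution
#'   (bp), truncated below at `read_length_min`.
#' @param read_length_min shortest simulated read (the assembler discards
#'   reads under 50 bp).
#' @param n_reads default reads per simulated sample.
#' @param gamma normalization exponent: read sampling weights are
#'   proportional to `abundance^gamma`; `gamma = 1` is a non-normalized
#'   library, `gamma < 1` flattens abundances as cDNA normalization does,
#'   `gamma = 0` is perfectly uniform.
#' @param k_min reads required before a transcript region is assembled
#'   into a contig; genes with fewer total reads stay as singletons.
#' @param seed integer seed making the whole ground truth reproducible.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 100L, n_paralog_pairs = 5L,
                       isoform_probability = 0.2,
                       exons_per_transcript = c(2L, 6L),
                       exon_length = c(99L, 399L),
                       utr_length = c(50L, 200L),
                       cassette_length = 100L,
                       abundance_meanlog = 0, abundance_sdlog = 1.5,
                       read_length_mean = 300, read_length_sd = 60,
                       read_length_min = 50L,
                       n_reads = 20000L, gamma = 1, k_min = 2L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_paralog_pairs = as.integer(n_paralog_pairs),
              isoform_probability = isoform_probability,
              exons_per_transcript = as.integer(exons_per_transcript),
              exon_length = as.integer(exon_length),
              utr_length = as.integer(utr_length),
              cassette_length = as.integer(cassette_length),
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              read_length_mean = read_length_mean,
              read_length_sd = read_length_sd,
              read_length_min = as.integer(read_length_min),
              n_reads = as.integer(n_reads), gamma = gamma,
              k_min = as.integer(k_min), seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes >= 1L, n_paralog_pairs >= 0L,
              2L * n_paralog_pairs <= n_genes,
              isoform_probability >= 0, isoform_probability <= 1,
              length(exons_per_transcript) == 2L,
              exons_per_transcript[1L] >= 1L,
              exons_per_transcript[1L] <= exons_per_transcript[2L],
              exon_length[1L] >= 9L, exon_length[1L] <= exon_length[2L],
              utr_length[1L] >= 1L, utr_length[1L] <= utr_length[2L],
              cassette_length >= 1L, gamma >= 0, gamma <= 1,
              k_min >= 1L, read_length_min >= 1L)
  })
  structure(cfg, class = "sim_config")
}

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

translate_codons <- function(coding) {
  n <- nchar(coding) %/% 3L
  codons <- substring(coding, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a ground-truth transcriptome
#'
#' Builds a reference proteome and a matching transcript set with known
#' exon structure: each gene has a 5' UTR, coding exons drawn to a
#' stop-free codon sequence (so the coding region translates exactly to
#' its reference protein), an optional non-coding cassette exon, and a 3'
#' UTR.  Genes drawn as isoform carriers get a second isoform lacking the
#' cassette.  Paralog pairs are made by copying a gene and replacing ~10%
#' of its codons; both members share the original's protein as their best
#' database hit under the emulated BLAST scorer.
#'
#' @param config a [sim_config()].
#' @return a list of class `ground_truth` with elements `config`,
#'   `proteins` (sequence table), `genes` (`gene_id`, `protein_id`,
#'   `blast_subject`, `paralog_of`, `has_isoform`), `transcripts`
#'   (`tx_id`, `gene_id`, `isoform`, `residues`, `length`, `cds_start`,
#'   `cds_end`, list column `segments`), and `abundance` (named by
#'   `tx_id`).
#' @export
simulate_transcriptome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, build_truth(config))
}

# uniform draw from an inclusive integer range (safe for degenerate ranges)
sample_range <- function(lo, hi, n = 1L) {
  if (lo == hi) rep.int(lo, n) else sample(seq.int(lo, hi), n, replace = TRUE)
}

build_truth <- function(cfg) {
  codon_pool <- sense_codons()
  n_orig <- cfg$n_genes - cfg$n_paralog_pairs
  genes <- vector("list", cfg$n_genes)

  make_gene <- function(gid) {
    n_ex <- sample_range(cfg$exons_per_transcript[1L],
                         cfg$exons_per_transcript[2L])
    ex_len <- sample_range(cfg$exon_length[1L], cfg$exon_length[2L], n_ex)
    ex_len <- ex_len - ex_len %% 3L  # keep exon boundaries on codons
    ex_len[ex_len < 9L] <- 9L
    n_codons <- sum(ex_len) %/% 3L
    coding <- paste(sample(codon_pool, n_codons, replace = TRUE),
                    collapse = "")
    list(gene_id = gid,
         utr5 = random_nt(sample_range(cfg$utr_length[1L],
                                       cfg$utr_length[2L])),
         utr3 = random_nt(sample_range(cfg$utr_length[1L],
                                       cfg$utr_length[2L])),
         cassette = random_nt(cfg$cassette_length),
         exon_len = ex_len, coding = coding,
         has_isoform = stats::runif(1L) < cfg$isoform_probability)
  }

  mutate_gene <- function(g, gid) {
    n_codons <- nchar(g$coding) %/% 3L
    n_mut <- max(1L, round(0.1 * n_codons))
    at <- sample.int(n_codons, n_mut)
    codons <- substring(g$coding, 3L * seq_len(n_codons) - 2L,
                        3L * seq_len(n_codons))
    codons[at] <- vapply(codons[at], function(cd) {
      sample(setdiff(codon_pool, cd), 1L)
    }, character(1L))
    g$coding <- paste(codons, collapse = "")
    g$gene_id <- gid
    g
  }

  for (i in seq_len(n_orig)) genes[[i]] <- make_gene(sprintf("gene%03d", i))
  paralog_of <- rep(NA_character_, cfg$n_genes)
  if (cfg$n_paralog_pairs > 0L) {
    for (j in seq_len(cfg$n_paralog_pairs)) {
      src <- genes[[j]]
      k <- n_orig + j
      genes[[k]] <- mutate_gene(src, sprintf("gene%03d", k))
      paralog_of[k] <- src$gene_id
    }
  }

  gene_rows <- list(); tx_rows <- list(); prot_rows <- list()
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    prot_id <- paste0("prot_", g$gene_id)
    subject <- if (is.na(paralog_of[i])) prot_id
               else paste0("prot_", paralog_of[i])
    prot_rows[[i]] <- data.frame(
      id = prot_id, description = paste("reference protein of", g$gene_id),
      residues = translate_codons(g$coding), role = "reference_protein",
      stringsAsFactors = FALSE)
    gene_rows[[i]] <- data.frame(
      gene_id = g$gene_id, protein_id = prot_id, blast_subject = subject,
      paralog_of = paralog_of[i], has_isoform = g$has_isoform,
      stringsAsFactors = FALSE)
    tx_rows[[i]] <- gene_transcripts(g)
  }
  transcripts <- do.call(rbind, tx_rows)
  rownames(transcripts) <- NULL
  abundance <- stats::setNames(
    stats::rlnorm(nrow(transcripts), cfg$abundance_meanlog,
                  cfg$abundance_sdlog),
    transcripts$tx_id)
  structure(list(config = cfg,
                 proteins = do.call(rbind, prot_rows),
                 genes = do.call(rbind, gene_rows),
                 transcripts = transcripts,
                 abundance = abundance),
            class = "ground_truth")
}

# Lay out the transcript(s) of one gene: 5'UTR, coding exons, optional
# cassette (long isoform only), 3'UTR.  Segment ids are shared between
# isoforms so the assembly emulator can pool reads across isoforms.
gene_transcripts <- function(g) {
  u5 <- nchar(g$utr5); cas <- nchar(g$cassette); u3 <- nchar(g$utr3)
  build <- function(with_cassette, isoform) {
    seg_id <- c(paste0(g$gene_id, "_u5"),
                paste0(g$gene_id, "_e", seq_along(g$exon_len)),
                if (with_cassette) paste0(g$gene_id, "_cas"),
                paste0(g$gene_id, "_u3"))
    seg_len <- c(u5, g$exon_len, if (with_cassette) cas, u3)
    seg_end <- cumsum(seg_len)
    seg_start <- seg_end - seg_len + 1L
    residues <- paste0(g$utr5, g$coding,
                       if (with_cassette) g$cassette else "", g$utr3)
    tx <- data.frame(
      tx_id = paste0("tx_", g$gene_id, "_", isoform),
      gene_id = g$gene_id, isoform = isoform, residues = residues,
      length = nchar(residues),
      cds_start = u5 + 1L, cds_end = u5 + nchar(g$coding),
      stringsAsFactors = FALSE)
    tx$segments <- list(data.frame(segment_id = seg_id, start = seg_start,
                                   end = seg_end, stringsAsFactors = FALSE))
    tx
  }
  if (g$has_isoform) rbind(build(TRUE, "long"), build(FALSE, "short"))
  else build(TRUE, "long")
}

#' Simulate reads from a ground truth
#'
#' Transcripts are sampled with probability proportional to
#' `abundance^gamma` (the normalization transform: `gamma = 1` leaves the
#' library as is, smaller values flatten it, `gamma = 0` samples
#' transcripts uniformly).  Read lengths follow the configured truncated
#' normal; the start position is uniform over the placements that fit, so
#' reads never run past the transcript end and never fall below the
#' minimum length (transcripts shorter than a drawn read yield the full
#' transcript).
#'
#' @param truth a `ground_truth` from [simulate_transcriptome()].
#' @param sample_label label stored in the `sample` column (e.g. `"N"`,
#'   `"NN"`).
#' @param n_reads number of reads.
#' @param gamma normalization exponent in `[0, 1]`; defaults to the
#'   config's value.
#' @param seed integer seed.
#' @return a read table with provenance: `id`, `sample`, `tx_id`,
#'   `start`, `length`, `residues`, `role`.
#' @export
simulate_reads <- function(truth, sample_label, n_reads = NULL,
                           gamma = NULL, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  cfg <- truth$config
  if (is.null(n_reads)) n_reads <- cfg$n_reads
  if (is.null(gamma)) gamma <- cfg$gamma
  stopifnot(n_reads >= 0L, gamma >= 0, gamma <= 1)
  if (n_reads == 0L) return(empty_read_table())
  withr::with_seed(seed, {
    w <- truth$abundance^gamma
    tx_idx <- sample.int(nrow(truth$transcripts), n_reads, replace = TRUE,
                         prob = w / sum(w))
    tx_len <- truth$transcripts$length[tx_idx]
    len <- pmax(cfg$read_length_min,
                round(stats::rnorm(n_reads, cfg$read_length_mean,
                                   cfg$read_length_sd)))
    len <- pmin(len, tx_len)
    start <- 1L + floor(stats::runif(n_reads) * (tx_len - len + 1L))
    data.frame(
      id = sprintf("%s_read%06d", sample_label, seq_len(n_reads)),
      sample = sample_label,
      tx_id = truth$transcripts$tx_id[tx_idx],
      start = as.integer(start), length = as.integer(len),
      residues = substring(truth$transcripts$residues[tx_idx], start,
                           start + len - 1L),
      role = "read", stringsAsFactors = FALSE)
  })
}

empty_read_table <- function() {
  data.frame(id = character(), sample = character(), tx_id = character(),
             start = integer(), length = integer(), residues = character(),
             role = character(), stringsAsFactors = FALSE)
}

#' Emulate the hierarchical assembly of provenance-tagged reads
#'
#' A behavioural stand-in for a cDNA assembler, assembling by read
#' provenance rather than overlap detection: within each gene, every
#' transcript segment (UTR, coding exon, cassette) attracting at least
#' `k_min` reads (by read midpoint) becomes a contig, truncated to the
#' span those reads cover; each expressed isoform's surviving contig path
#' becomes an isotig (isoforms collapsing to the same path yield one
#' isotig); the isotigs of a gene form one isogroup.  Reads in
#' under-covered segments are returned as singletons, so every input read
#' is either a contig member or a singleton.
#'
#' @param reads a provenance-tagged read table ([simulate_reads()]).
#' @param truth the `ground_truth` the reads came from.
#' @param k_min reads required to assemble a segment region; defaults to
#'   the config's value.
#' @return a list with `assembly` (an [assembly_set()] whose
#'   `isotig_map` attribute records, per isotig, the source transcript
#'   and the transcript-coordinate spans of its contigs) and
#'   `singleton_reads`.
#' @export
emulate_assembly <- function(reads, truth, k_min = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (is.null(k_min)) k_min <- truth$config$k_min
  tx <- truth$transcripts
  tx_row <- match(reads$tx_id, tx$tx_id)
  if (anyNA(tx_row)) {
    stop("read '", reads$id[is.na(tx_row)][1L],
         "' has no provenance in the ground truth")
  }
  # a read contributes coverage to every segment it overlaps; its midpoint
  # segment decides its fate (contig member vs singleton)
  mid <- reads$start + (reads$length - 1L) %/% 2L
  mid_seg <- character(nrow(reads))
  ov_read <- list(); ov_seg <- list(); ov_lo <- list(); ov_hi <- list()
  for (i in seq_len(nrow(reads))) {
    segs <- tx$segments[[tx_row[i]]]
    r_end <- reads$start[i] + reads$length[i] - 1L
    j <- which(segs$start <= r_end & segs$end >= reads$start[i])
    mid_seg[i] <- segs$segment_id[
      which(segs$start <= mid[i] & mid[i] <= segs$end)[1L]]
    ov_read[[i]] <- rep.int(i, length(j))
    ov_seg[[i]] <- segs$segment_id[j]
    ov_lo[[i]] <- pmax(reads$start[i], segs$start[j]) - segs$start[j] + 1L
    ov_hi[[i]] <- pmin(r_end, segs$end[j]) - segs$start[j] + 1L
  }
  ov <- data.frame(read = unlist(ov_read), segment_id = unlist(ov_seg),
                   lo = unlist(ov_lo), hi = unlist(ov_hi),
                   stringsAsFactors = FALSE)

  seg_counts <- table(ov$segment_id)
  passing <- names(seg_counts)[seg_counts >= k_min]
  singleton_idx <- which(!(mid_seg %in% passing))

  contig_rows <- list(); contig_seq <- list()
  for (s in passing) {
    i <- which(ov$segment_id == s)
    lo <- min(ov$lo[i]); hi <- max(ov$hi[i])
    # segment residues from any transcript containing it
    r1 <- tx_row[ov$read[i[1L]]]
    segs <- tx$segments[[r1]]
    j <- match(s, segs$segment_id)
    seq <- substring(tx$residues[r1], segs$start[j] + lo - 1L,
                     segs$start[j] + hi - 1L)
    contig_rows[[s]] <- data.frame(
      contig_id = paste0("ctg_", s), segment_id = s,
      length = hi - lo + 1L, local_lo = lo, local_hi = hi,
      n_reads = length(i), read_bp = sum(reads$length[ov$read[i]]),
      stringsAsFactors = FALSE)
    contig_seq[[paste0("ctg_", s)]] <- seq
  }
  contig_info <- if (length(contig_rows)) do.call(rbind, contig_rows)
                 else data.frame(contig_id = character(),
                                 segment_id = character(),
                                 length = integer(), local_lo = integer(),
                                 local_hi = integer(), n_reads = integer(),
                                 read_bp = numeric(),
                                 stringsAsFactors = FALSE)
  rownames(contig_info) <- NULL

  # isotigs: per expressed transcript, the path of passing contigs
  expressed <- unique(reads$tx_id)
  mem_rows <- list(); iso_seq_rows <- list(); map_rows <- list()
  for (g in unique(tx$gene_id[tx$tx_id %in% expressed])) {
    g_tx <- tx[tx$gene_id == g & tx$tx_id %in% expressed, , drop = FALSE]
    paths <- list()
    for (r in seq_len(nrow(g_tx))) {
      segs <- g_tx$segments[[r]]
      keep <- segs$segment_id %in% passing
      if (!any(keep)) next
      path <- paste0("ctg_", segs$segment_id[keep])
      key <- paste(path, collapse = "|")
      if (!key %in% names(paths)) {
        paths[[key]] <- list(path = path, tx_row = r)
      }
    }
    if (length(paths) == 0L) next
    for (k in seq_along(paths)) {
      p <- paths[[k]]
      iso_id <- sprintf("iso_%s_%02d", g, k)
      segs <- g_tx$segments[[p$tx_row]]
      ci <- contig_info[match(sub("^ctg_", "", p$path),
                              contig_info$segment_id), , drop = FALSE]
      seg_j <- match(ci$segment_id, segs$segment_id)
      tx_spans <- data.frame(
        contig_id = ci$contig_id,
        tx_start = segs$start[seg_j] + ci$local_lo - 1L,
        tx_end = segs$start[seg_j] + ci$local_hi - 1L,
        q_offset = cumsum(c(0L, utils::head(ci$length, -1L))),
        stringsAsFactors = FALSE)
      mem_rows[[iso_id]] <- data.frame(isotig_id = iso_id, isogroup_id =
                                         paste0("grp_", g),
                                       stringsAsFactors = FALSE)
      mem_rows[[iso_id]]$contig_ids <- list(p$path)
      iso_seq_rows[[iso_id]] <- data.frame(
        id = iso_id, description = paste0("isogroup grp_", g),
        residues = paste(unlist(contig_seq[p$path]), collapse = ""),
        role = "isotig", stringsAsFactors = FALSE)
      map_rows[[iso_id]] <- data.frame(
        isotig_id = iso_id, gene_id = g, tx_id = g_tx$tx_id[p$tx_row],
        stringsAsFactors = FALSE)
      map_rows[[iso_id]]$spans <- list(tx_spans)
    }
  }

  membership <- if (length(mem_rows)) do.call(rbind, mem_rows)
                else {
                  m <- data.frame(isotig_id = character(),
                                  isogroup_id = character(),
                                  stringsAsFactors = FALSE)
                  m$contig_ids <- list(); m
                }
  rownames(membership) <- NULL
  iso_seqs <- if (length(iso_seq_rows)) do.call(rbind, iso_seq_rows)
              else empty_seq_table()
  # drop contigs that ended up in no isotig path (none by construction,
  # but keep contig_info restricted to referenced contigs for validity)
  singleton_reads <- reads[singleton_idx, , drop = FALSE]
  rownames(singleton_reads) <- NULL
  asm <- assembly_set(membership, iso_seqs,
                      contig_info[, c("contig_id", "length", "n_reads",
                                      "read_bp")],
                      singleton_seqs = singleton_reads[,
                        c("id", "sample", "tx_id", "start", "length",
                          "residues", "role"), drop = FALSE])
  attr(asm, "isotig_map") <- if (length(map_rows)) do.call(rbind, map_rows)
                             else NULL
  list(assembly = asm, singleton_reads = singleton_reads)
}

#' Emulate BLASTX hits of assembled sequences and singletons
#'
#' Each isotig and singleton read receives one hit against its gene's
#' best-subject reference protein, with exact coordinates of the covered
#' coding span: subject coordinates are the covered codons, the e-value
#' decreases monotonically with aligned length (`10^(-codons/2)`, floored
#' at `1e-180`) and the bitscore increases with it.  The e-values are
#' rank-faithful stand-ins -- downstream logic uses only their ordering
#' and thresholds.  Paralog-pair queries hit the shared subject with
#' overlapping subject spans, and mutant-copy queries carry a ~90%
#' identity.  Queries covering no coding codon obtain no hit.
#'
#' @param assembly an emulated [assembly_set()] (with its `isotig_map`
#'   attribute).
#' @param singleton_reads provenance-tagged singleton reads.
#' @param truth the `ground_truth`.
#' @return a hit table in the [read_blast_tab()] layout, `subject_len`
#'   filled.
#' @export
emulate_blast <- function(assembly, singleton_reads, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  tx <- truth$transcripts
  genes <- truth$genes
  prot_len <- stats::setNames(nchar(truth$proteins$residues),
                              truth$proteins$id)
  rows <- list()

  hit_row <- function(query_id, gene_id, q_start, q_end, s_start, s_end) {
    gi <- match(gene_id, genes$gene_id)
    subject <- genes$blast_subject[gi]
    ident <- if (is.na(genes$paralog_of[gi])) 99.0 else 90.0
    aln <- s_end - s_start + 1L
    data.frame(query_id = query_id, subject_id = subject,
               pct_identity = ident, aln_len = aln,
               mismatches = as.integer(round(aln * (1 - ident / 100))),
               gap_opens = 0L,
               q_start = q_start, q_end = q_end,
               s_start = s_start, s_end = s_end,
               evalue = max(10^(-aln / 2), 1e-180),
               bitscore = 2 * aln,
               subject_len = unname(prot_len[subject]),
               q_strand = "plus", s_strand = "plus",
               stringsAsFactors = FALSE)
  }

  imap <- attr(assembly, "isotig_map")
  if (!is.null(imap)) {
    for (i in seq_len(nrow(imap))) {
      ti <- match(imap$tx_id[i], tx$tx_id)
      cds <- c(tx$cds_start[ti], tx$cds_end[ti])
      spans <- imap$spans[[i]]
      lo <- pmax(spans$tx_start, cds[1L])
      hi <- pmin(spans$tx_end, cds[2L])
      cov <- which(lo <= hi)
      if (length(cov) == 0L) next
      first <- cov[1L]; last <- cov[length(cov)]
      q_start <- spans$q_offset[first] + (lo[first] - spans$tx_start[first]) + 1L
      q_end <- spans$q_offset[last] + (hi[last] - spans$tx_start[last]) + 1L
      s_start <- (lo[first] - cds[1L]) %/% 3L + 1L
      s_end <- (hi[last] - cds[1L]) %/% 3L + 1L
      rows[[length(rows) + 1L]] <-
        hit_row(imap$isotig_id[i], imap$gene_id[i], q_start, q_end,
                s_start, s_end)
    }
  }

  if (nrow(singleton_reads)) {
    ti <- match(singleton_reads$tx_id, tx$tx_id)
    if (anyNA(ti)) {
      stop("singleton '", singleton_reads$id[is.na(ti)][1L],
           "' has no provenance in the ground truth")
    }
    for (i in seq_len(nrow(singleton_reads))) {
      cds <- c(tx$cds_start[ti[i]], tx$cds_end[ti[i]])
      r_start <- singleton_reads$start[i]
      r_end <- r_start + singleton_reads$length[i] - 1L
      lo <- max(r_start, cds[1L]); hi <- min(r_end, cds[2L])
      if (hi - lo + 1L < 3L) next
      rows[[length(rows) + 1L]] <-
        hit_row(singleton_reads$id[i], tx$gene_id[ti[i]],
                lo - r_start + 1L, hi - r_start + 1L,
                (lo - cds[1L]) %/% 3L + 1L, (hi - cds[1L]) %/% 3L + 1L)
    }
  }
  if (length(rows) == 0L) return(empty_blast_table())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Adapter factories for the discovery-curve machinery
#'
#' `emulated_assembler()` closes over a ground truth and returns the
#' assembler-adapter callable used by [discovery_curve()];
#' `emulated_blaster()` returns the matching hit-table callable.
#'
#' @param truth a `ground_truth`.
#' @param k_min contig threshold for the emulated assembly.
#' @return a function of the adapter contract.
#' @export
emulated_assembler <- function(truth, k_min = NULL) {
  force(truth); force(k_min)
  function(reads) emulate_assembly(reads, truth, k_min)
}

#' @rdname emulated_assembler
#' @export
emulated_blaster <- function(truth) {
  force(truth)
  function(assembly, singleton_reads) {
    emulate_blast(assembly, singleton_reads, truth)
  }
}
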