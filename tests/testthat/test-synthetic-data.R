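test_that("ground truth is deterministic and structurally sound", {
  cfg <- sim_config(n_genes = 12, n_paralog_pairs = 2,
                    isoform_probability = 0.5, seed = 5)
  t1 <- simulate_transcriptome(cfg)
  t2 <- simulate_transcriptome(cfg)
  expect_equal(t1, t2)

  expect_equal(nrow(t1$genes), 12L)
  expect_equal(nrow(t1$proteins), 12L)
  # every coding region translates exactly to its reference protein
  for (i in seq_len(nrow(t1$transcripts))) {
    tx <- t1$transcripts[i, ]
    coding <- substr(tx$residues, tx$cds_start, tx$cds_end)
    prot_id <- t1$genes$protein_id[t1$genes$gene_id == tx$gene_id]
    expect_equal(
      as.character(Biostrings::translate(Biostrings::DNAString(coding))),
      t1$proteins$residues[t1$proteins$id == prot_id])
  }
})

test_that("isoform carriers differ by exactly the cassette length", {
  cfg <- sim_config(n_genes = 6, n_paralog_pairs = 0,
                    isoform_probability = 1, cassette_length = 100L, seed = 9)
  truth <- simulate_transcriptome(cfg)
  for (g in truth$genes$gene_id) {
    tx <- truth$transcripts[truth$transcripts$gene_id == g, ]
    expect_equal(nrow(tx), 2L)
    expect_equal(abs(diff(tx$length)), 100L)
    expect_equal(tx$cds_start[1], tx$cds_start[2])  # same protein both ways
  }

  none <- simulate_transcriptome(sim_config(n_genes = 3,
                                            n_paralog_pairs = 0,
                                            isoform_probability = 0,
                                            seed = 1))
  expect_equal(nrow(none$transcripts), 3L)
  expect_equal(nrow(none$proteins), 3L)
})

test_that("paralog pairs encode similar proteins sharing a blast subject", {
  cfg <- sim_config(n_genes = 8, n_paralog_pairs = 3, seed = 10)
  truth <- simulate_transcriptome(cfg)
  pairs <- truth$genes[!is.na(truth$genes$paralog_of), ]
  expect_equal(nrow(pairs), 3L)
  for (i in seq_len(nrow(pairs))) {
    orig <- truth$genes[truth$genes$gene_id == pairs$paralog_of[i], ]
    expect_equal(pairs$blast_subject[i], orig$protein_id)
    p1 <- truth$proteins$residues[truth$proteins$id == pairs$protein_id[i]]
    p2 <- truth$proteins$residues[truth$proteins$id == orig$protein_id]
    expect_equal(nchar(p1), nchar(p2))
    ident <- mean(strsplit(p1, "")[[1]] == strsplit(p2, "")[[1]])
    expect_gte(ident, 0.8)
  }
})

test_that("read simulation respects weights, lengths and determinism", {
  cfg <- sim_config(n_genes = 10, n_paralog_pairs = 0, seed = 3)
  truth <- simulate_transcriptome(cfg)
  expect_equal(nrow(simulate_reads(truth, "N", 0, seed = 1)), 0L)

  r1 <- simulate_reads(truth, "N", 500, gamma = 0.5, seed = 2)
  expect_equal(simulate_reads(truth, "N", 500, gamma = 0.5, seed = 2), r1)
  expect_true(all(r1$length >= 50L))
  tx_len <- truth$transcripts$length[match(r1$tx_id,
                                           truth$transcripts$tx_id)]
  expect_true(all(r1$start + r1$length - 1L <= tx_len))
  expect_equal(nchar(r1$residues), r1$length)

  # gamma = 0 samples transcripts uniformly: counts within binomial noise
  r0 <- simulate_reads(truth, "N", 5000, gamma = 0, seed = 4)
  counts <- table(factor(r0$tx_id, levels = truth$transcripts$tx_id))
  expect_true(max(abs(counts - 500)) < 5 * sqrt(500))
})

test_that("assembly emulation forms the hierarchy and routes every read", {
  cfg <- sim_config(n_genes = 5, n_paralog_pairs = 0,
                    isoform_probability = 1, abundance_sdlog = 0.3, seed = 6)
  truth <- simulate_transcriptome(cfg)
  reads <- simulate_reads(truth, "NN", 1500, gamma = 1, seed = 7)
  res <- emulate_assembly(reads, truth, k_min = 1)
  s <- summarize_assembly(res$assembly)
  expect_equal(s$n_isogroups, 5L)
  expect_equal(s$n_isotigs, 10L)  # saturating coverage: both isoforms out
  # read accounting: every read is a contig member or a singleton
  # (boundary-spanning reads contribute coverage to both flanking contigs,
  # so contig read counts can only exceed the member count)
  expect_gte(sum(res$assembly$contig_info$n_reads),
             nrow(reads) - nrow(res$singleton_reads))
  expect_true(all(res$singleton_reads$id %in% reads$id))
  # contig read_bp is consistent with coverage >= 1 read per bp of span
  expect_true(all(res$assembly$contig_info$read_bp >=
                    res$assembly$contig_info$n_reads))

  # a gene with a single read under k_min = 2 stays a singleton
  one <- reads[1, , drop = FALSE]
  res1 <- emulate_assembly(one, truth, k_min = 2)
  expect_equal(nrow(res1$assembly$membership), 0L)
  expect_equal(res1$singleton_reads$id, one$id)

  # no reads -> empty assembly
  res0 <- emulate_assembly(reads[0, ], truth, k_min = 2)
  expect_equal(nrow(res0$assembly$membership), 0L)
})

test_that("emulated hits carry exact coordinates of the covered coding span", {
  cfg <- sim_config(n_genes = 4, n_paralog_pairs = 0,
                    isoform_probability = 0, abundance_sdlog = 0.3, seed = 8)
  truth <- simulate_transcriptome(cfg)
  reads <- simulate_reads(truth, "NN", 2000, gamma = 1, seed = 9)
  res <- emulate_assembly(reads, truth, k_min = 1)
  hits <- emulate_blast(res$assembly, res$singleton_reads, truth)

  # saturating coverage: each isotig covers its whole CDS, so OHR = 1
  iso_hits <- hits[hits$query_id %in% res$assembly$membership$isotig_id, ]
  ohr <- ortholog_hit_ratio(select_top_hits(iso_hits), "protein")
  prot_len <- nchar(truth$proteins$residues)
  expect_equal(ohr$ratio, rep(1, nrow(ohr)), tolerance = 0.02)
  expect_true(all(iso_hits$evalue <= 1e-10))
  expect_true(all(iso_hits$s_start == 1L))
  expect_setequal(iso_hits$s_end, prot_len)

  # singleton hits: OHR equals the read's codon overlap with the CDS
  sng <- res$singleton_reads
  if (nrow(sng)) {
    sh <- hits[hits$query_id %in% sng$id, ]
    expect_true(all(sh$aln_len == sh$s_end - sh$s_start + 1L))
  }
})

test_that("a partially covered gene yields a proportional ortholog hit ratio", {
  cfg <- sim_config(n_genes = 1, n_paralog_pairs = 0,
                    isoform_probability = 0, exons_per_transcript = c(4L, 4L),
                    exon_length = c(300L, 300L), utr_length = c(60L, 60L),
                    seed = 11)
  truth <- simulate_transcriptome(cfg)
  tx <- truth$transcripts[1, ]
  # one hand-placed read covering roughly the first half of the CDS
  half <- data.frame(id = "r1", sample = "NN", tx_id = tx$tx_id,
                     start = tx$cds_start, length = 600L,
                     residues = substr(tx$residues, tx$cds_start,
                                       tx$cds_start + 599L),
                     role = "read", stringsAsFactors = FALSE)
  res <- emulate_assembly(half, truth, k_min = 1)
  hits <- emulate_blast(res$assembly, res$singleton_reads, truth)
  ohr <- ortholog_hit_ratio(hits, "protein")
  # 600 of 1200 coding bases covered: ratio 0.5 within one codon of rounding
  expect_equal(ohr$ratio, 0.5, tolerance = 1 / 400)
})

test_that("paralog pairs produce overlapping spans counted as two genes", {
  cfg <- sim_config(n_genes = 2, n_paralog_pairs = 1,
                    isoform_probability = 0, abundance_sdlog = 0.3, seed = 12)
  truth <- simulate_transcriptome(cfg)
  reads <- simulate_reads(truth, "NN", 1500, gamma = 1, seed = 13)
  res <- emulate_assembly(reads, truth, k_min = 1)
  hits <- emulate_blast(res$assembly, res$singleton_reads, truth)
  top <- select_top_hits(
    hits[hits$query_id %in% longest_isotig_per_isogroup(res$assembly), ])
  expect_equal(length(unique(top$subject_id)), 1L)  # shared best subject
  tally <- unique_gene_tally(top, "interval_aware")
  expect_equal(tally$total_unique_genes, 2L)
  expect_equal(tally$per_subject$classification, "paralogs")
})
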