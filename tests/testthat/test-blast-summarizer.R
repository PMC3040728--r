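test_that("e-value filtering keeps hits at or below the cutoff, in order", {
  h <- toy_hits(c("q1", "q2"), c("s1", "s2"), c(1e-12, 1e-8))
  expect_equal(filter_by_evalue(h, 1e-10)$query_id, "q1")
  expect_equal(nrow(filter_by_evalue(h, 1)), 2L)
  expect_equal(nrow(filter_by_evalue(h[0, ], 1e-10)), 0L)
})

test_that("top-hit selection breaks ties by e-value, bitscore, then input order", {
  h <- toy_hits(c("q1", "q1"), c("s1", "s2"), c(1e-5, 1e-20))
  expect_equal(select_top_hits(h)$subject_id, "s2")

  tie <- toy_hits(c("q1", "q1"), c("s1", "s2"), c(1e-20, 1e-20),
                  bitscore = c(100, 200))
  expect_equal(select_top_hits(tie)$subject_id, "s2")

  both <- toy_hits(c("q1", "q1"), c("s1", "s2"), 1e-20, bitscore = 150)
  expect_equal(select_top_hits(both)$subject_id, "s1")
})

test_that("shared-subject intervals classify as fragments, paralogs or mixed", {
  d <- classify_shared_subject(c(1, 150), c(100, 250))
  expect_equal(d, list(classification = "merged_fragments", gene_count = 1L))

  o <- classify_shared_subject(c(1, 50), c(100, 150))
  expect_equal(o, list(classification = "paralogs", gene_count = 2L))

  # max depth 2; minimal chain partition {[1,100],[150,250]} + {[90,160]}
  m <- classify_shared_subject(c(1, 90, 150), c(100, 160, 250))
  expect_equal(m, list(classification = "mixed", gene_count = 2L))

  expect_equal(classify_shared_subject(5, 9)$classification, "single")
  expect_error(classify_shared_subject(10, 5))
})

test_that("overlap tolerance ignores micro-overlaps", {
  # 1 shared position: overlapping at tolerance 0, disjoint at tolerance 1
  expect_equal(classify_shared_subject(c(1, 100), c(100, 200))$gene_count, 2L)
  expect_equal(
    classify_shared_subject(c(1, 100), c(100, 200), tolerance = 1L)$gene_count,
    1L)
})

test_that("chain-partition gene counts equal the exhaustive minimum", {
  withr::with_seed(77, {
    for (trial in 1:400) {
      n <- sample.int(8, 1)
      starts <- sample.int(60, n, replace = TRUE)
      ends <- starts + sample.int(30, n, replace = TRUE) - 1L
      got <- classify_shared_subject(starts, ends)$gene_count
      expect_identical(got, brute_min_chains(starts, ends),
                       info = paste(starts, ends, collapse = ";"))
    }
  })
})

test_that("unique-gene tally applies the per-class counting rules", {
  # 3 queries on 3 distinct subjects
  h3 <- toy_hits(paste0("q", 1:3), paste0("s", 1:3), 1e-20)
  t3 <- unique_gene_tally(select_top_hits(h3), "interval_aware")
  expect_equal(t3$total_unique_genes, 3L)

  # singletons on one subject collapse to one regardless of coordinates
  hs <- toy_hits(paste0("q", 1:3), "s1", 1e-20,
                 s_start = c(1L, 200L, 50L), s_end = c(100L, 300L, 150L))
  ts <- unique_gene_tally(select_top_hits(hs), "one_per_subject")
  expect_equal(ts$total_unique_genes, 1L)
  expect_equal(ts$n_merged_away, 2L)

  # S1 has disjoint spans (1 gene), S2 overlapping spans (2 genes)
  hm <- toy_hits(paste0("q", 1:4), c("S1", "S1", "S2", "S2"), 1e-20,
                 s_start = c(1L, 60L, 1L, 40L),
                 s_end = c(50L, 90L, 80L, 120L))
  tm <- unique_gene_tally(select_top_hits(hm), "interval_aware")
  expect_equal(tm$total_unique_genes, 3L)
  expect_equal(sum(tm$per_subject$n_queries), 4L)
})

test_that("tally totals respect their structural bounds and input order", {
  withr::with_seed(31, {
    for (trial in 1:30) {
      nq <- sample(3:20, 1)
      h <- toy_hits(paste0("q", seq_len(nq)),
                    sample(paste0("s", 1:6), nq, replace = TRUE),
                    1e-20,
                    s_start = sample.int(200, nq, replace = TRUE))
      h$s_end <- h$s_start + sample.int(80, nq, replace = TRUE)
      top <- select_top_hits(h)
      one <- unique_gene_tally(top, "one_per_subject")
      ia <- unique_gene_tally(top, "interval_aware")
      n_subj <- length(unique(top$subject_id))
      expect_equal(one$total_unique_genes, n_subj)
      expect_gte(ia$total_unique_genes, n_subj)
      expect_lte(ia$total_unique_genes, nrow(top))
      shuf <- top[sample.int(nrow(top)), ]
      expect_equal(unique_gene_tally(shuf, "interval_aware")$total_unique_genes,
                   ia$total_unique_genes)
    }
  })
})

test_that("species breakdown counts taxa and pools rare ones", {
  top <- toy_hits(paste0("q", 1:3), c("s1", "s2", "s3"), 1e-20)
  taxa <- c(s1 = "A", s2 = "A", s3 = "B")
  bd <- species_breakdown(top, taxa)
  expect_equal(bd$count[bd$taxon == "A"], 2L)
  bd2 <- species_breakdown(top, taxa, min_count = 2L)
  expect_equal(bd2$count[bd2$taxon == "other"], 1L)
  bd3 <- species_breakdown(top, c(s1 = "A"))
  expect_equal(sum(bd3$count[bd3$taxon == "unknown"]), 2L)
  expect_equal(nrow(species_breakdown(top[0, ], taxa)), 0L)
})
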