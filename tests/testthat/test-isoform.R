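test_that("isoform-pair detection requires a single-contig path difference", {
  asm <- toy_assembly()  # g1: i1 = c1,c2,c3 vs i2 = c1,c3 -> differs by c2
  pairs <- find_isoform_pairs(asm)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$differing_contig_id, "c2")
  expect_equal(pairs$isotig_long, "i1")
  expect_equal(pairs$size_difference, 100L)

  # disjoint paths are excluded
  asm2 <- toy_assembly()
  asm2$membership$contig_ids[[2]] <- c("c4", "c3")
  expect_equal(nrow(find_isoform_pairs(asm2)), 0L)

  # isogroups with three isotigs are excluded ("exactly two")
  mem3 <- data.frame(isotig_id = c("i1", "i2", "i4"),
                     isogroup_id = "g1", stringsAsFactors = FALSE)
  mem3$contig_ids <- list(c("c1", "c2", "c3"), c("c1", "c3"), c("c1"))
  asm3 <- toy_assembly()
  seqs3 <- asm3$isotig_seqs
  seqs3$id[3] <- "i4"
  asm3 <- assembly_set(mem3, seqs3, asm3$contig_info)
  expect_equal(nrow(find_isoform_pairs(asm3)), 0L)
})

test_that("isoform pairs are invariant to isotig order within the isogroup", {
  asm <- toy_assembly()
  asm$membership <- asm$membership[c(2, 1, 3), ]
  pairs <- find_isoform_pairs(asm)
  expect_equal(pairs$isotig_long, "i1")
  expect_equal(pairs$isotig_short, "i2")
})

test_that("amplicon prediction enumerates exact F/R-site combinations", {
  body <- strrep("G", 578)
  tpl <- data.frame(id = "t1", description = "",
                    residues = paste0("AAACCCTTTA", body, "TAGGGTTTAAAC"),
                    role = "isotig", stringsAsFactors = FALSE)
  # forward at position 1; reverse primer GTTTAAACCC rc = GGGTTTAAAC ends at 600
  prods <- predict_amplicons(tpl, "AAACCCTTTA", "GTTTAAACCC")
  expect_equal(prods$product_size, 600L)
  expect_equal(prods$f_start, 1L)
  expect_equal(prods$r_end, 600L)

  # a 100 bp insertion between primer sites shifts the product by exactly 100
  tpl2 <- tpl
  tpl2$id <- "t2"
  tpl2$residues <- paste0("AAACCCTTTA", strrep("A", 100), body,
                          "TAGGGTTTAAAC")
  both <- predict_amplicons(rbind(tpl, tpl2), "AAACCCTTTA", "GTTTAAACCC")
  expect_equal(diff(both$product_size), 100L)

  # absent forward primer: no product
  expect_equal(nrow(predict_amplicons(tpl, "TTTTTTTTTT", "GTTTAAACCC")), 0L)

  expect_error(predict_amplicons(tpl, "AAACCCTTT", "GTTTAAACCC"), "shorter")
  expect_error(predict_amplicons(tpl, "AAACCCTTTN", "GTTTAAACCC"),
               "degenerate")
})

test_that("amplicon products match brute-force substring scanning", {
  rc_base <- function(x) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }
  withr::with_seed(21, {
    for (trial in 1:25) {
      n <- sample(200:2000, 1)
      seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                   collapse = "")
      f_at <- sample.int(n - 120L, 1)
      r_at <- f_at + sample(40:100, 1)
      fwd <- substr(seq, f_at, f_at + 11L)
      rev_site <- substr(seq, r_at, r_at + 11L)
      rev_primer <- rc_base(rev_site)
      tpl <- data.frame(id = "t", description = "", residues = seq,
                        role = "isotig", stringsAsFactors = FALSE)
      got <- predict_amplicons(tpl, fwd, rev_primer)
      # oracle: scan every position for exact matches of both sites
      starts_f <- which(vapply(seq_len(n - 11L), function(i)
        substr(seq, i, i + 11L) == fwd, logical(1)))
      starts_r <- which(vapply(seq_len(n - 11L), function(i)
        substr(seq, i, i + 11L) == rev_site, logical(1)))
      want <- sort(unlist(lapply(starts_f, function(fs) {
        re <- starts_r[starts_r >= fs] + 11L
        re - fs + 1L
      })))
      expect_equal(sort(got$product_size), as.integer(want))
    }
  })
})

test_that("band comparison assigns the four support statuses", {
  expect_equal(compare_bands(c(300, 400), c(300, 400))$status,
               "all_predicted_seen")
  expect_equal(compare_bands(c(300, 400), c(300, 400, 650))$status,
               "predicted_seen_plus_extras")
  expect_equal(compare_bands(c(300, 400), c(300))$status, "partial")
  expect_equal(compare_bands(c(300, 400), c(700))$status, "unsupported")
  # tolerance 0 with identical lists always fully supports
  expect_equal(compare_bands(c(100, 200), c(200, 100), 0)$status,
               "all_predicted_seen")
  # 10% tolerance: 330 matches 300
  expect_equal(compare_bands(300, 330)$status, "all_predicted_seen")
  expect_equal(compare_bands(300, 331)$status, "unsupported")
})

test_that("band-case summaries report the single-product false-positive rate", {
  # 11 cases predicting two bands: 7 fully seen, 2 with extras, 1 partial
  # (two products, one of predicted size), 1 yielding a single product
  cases <- c(
    lapply(1:7, function(i) list(predicted = c(300, 400),
                                 observed = c(300, 400))),
    lapply(1:2, function(i) list(predicted = c(300, 400),
                                 observed = c(300, 400, 650))),
    list(list(predicted = c(300, 400), observed = c(300, 700))),
    list(list(predicted = c(300, 400), observed = 300)))
  s <- score_band_cases(cases)
  expect_equal(s$single_product_rate, 1 / 11)
  expect_equal(unname(s$report["pct_single_product"]), 9.1)
  expect_equal(sum(s$per_case$status == "predicted_seen_plus_extras"), 2L)
})
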