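Package: transurvey
Title: Post-Assembly Analysis of De Novo 454 Transcriptome Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis layer that follows de novo assembly of a
    454 pyrosequencing transcriptome survey: assembly accounting over the
    contig/isotig/isogroup hierarchy (N50, length histograms, per-contig
    coverage), collapsing of top BLAST hits into unique gene models with
    overlap-aware separation of transcript fragments from candidate paralogs,
    ortholog-hit-ratio completeness assessment, gene-discovery saturation
    curves from seeded read subsampling, comparison of normalized and
    non-normalized cDNA libraries with Fisher/FDR GO-term enrichment, and
    in-silico validation of assembler-predicted splice isoforms via amplicon
    size prediction.  A seeded synthetic-data generator emulates the full
    chain (reference proteome, transcripts with isoforms and paralog pairs,
    log-normal abundances with a normalization transform, reads, assembly
    hierarchy, and BLAST-tabular hits) so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
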