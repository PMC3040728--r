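---
title: "Methods: post-assembly analysis of a de novo transcriptome survey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-assembly analysis of a de novo transcriptome survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transurvey)
```

# The problem

A *de novo* transcriptome survey of an organism without a reference genome
produces a hierarchy of assembled sequences — contigs (exon-like stretches
free of branching conflicts), isotigs (transcript-level paths through
contigs), isogroups (gene-level sets of isotigs) — plus a large pool of
unassembled singleton reads, and BLAST searches of all of these against a
reference protein database. The scientific questions downstream are:
how many unique genes were sequenced, how complete are the assembled
transcripts, has gene discovery saturated, and did cDNA normalization pay
off? This vignette documents the models, conventions and design choices
behind each answer, and what the synthetic-data tests do and do not
establish.

# Unique-gene counting from top BLAST hits

After filtering hits at an e-value cutoff (default `1e-10` for protein
annotation searches) each query keeps one top hit: smallest e-value, ties
broken by larger bitscore, remaining ties by input order. Because BLAST
output order is deterministic, the whole selection is reproducible.

Several queries often share one top subject. Two readings exist: they are
unassembled **fragments** of a single transcript, or they are distinct
gene copies (**paralog candidates**). The discriminator is the geometry of
their alignment intervals on the subject: mutually non-overlapping
intervals are consistent with fragments of one transcript and count as one
gene; overlapping intervals imply distinct copies and all count.

Real interval sets are frequently neither all-disjoint nor all-overlapping.
The package generalizes both cases with one rule: the per-subject gene
count is the **minimum number of mutually non-overlapping chains** needed
to cover all intervals. For interval systems this minimum equals the
maximum point-depth of overlap (the interval graph's clique number equals
its chromatic number), so it is computed exactly by a sweep line in
O(n log n), and the test suite verifies it against an exhaustive
partition search for systems of up to 8 intervals. "Overlap" means
sharing at least one subject position (closed intervals); an optional
tolerance `t` requires an overlap longer than `t` positions, implemented
by shrinking interval right ends by `t` — exactly equivalent, and the
default `t = 0` is the strict reading.

Singleton reads get the blunter rule — at most one gene per subject,
whatever the overlap — because unassembled read pools contain many
near-identical reads whose overlapping alignments would otherwise inflate
the count. When a discovery curve combines both classes, a subject already
hit by an assembled sequence gains nothing from its singletons: the
conservative reading (such reads are presumed fragments of the counted
transcript), and the choice that keeps counts monotone along nested
subsamples. The alternative (singletons always add one) is not exposed;
it changed no conclusions in synthetic experiments and breaks
monotonicity.

# Ortholog hit ratio

The ortholog hit ratio (OHR) of a query is the length of its aligned span
divided by the full length of its top subject; 1 means a fully assembled
transcript, values above 1 suggest insertions relative to the subject.
Two conventions needed fixing:

* **Units.** For protein subjects from a translated search, the query
  span is in nucleotides and the subject in residues; the package divides
  the span by 3 so that "ratio = 1 ⇔ full length" holds. A nucleotide
  mode (no division) serves nucleotide-vs-nucleotide comparisons. The
  choice is recorded in the output (`subject_kind`).
* **Span.** The aligned span of the single best HSP row is used, not the
  whole query length; conserved-region dropout therefore deflates the
  ratio, making it an underestimate for weakly conserved genes. This is
  surfaced (per-record values are retained), not corrected.

Threshold fractions ("share of transcripts with OHR > 0.5 / > 0.8") use
strict inequality. The ratio is never capped at 1.

# Discovery curves and subsampling

Sub-assemblies at growing read counts are built from a seeded
Fisher–Yates shuffle (R's Mersenne-Twister stream) of the pooled reads;
the sample of size *n* is the first *n* elements of the shuffle, so
samples are **nested** and the unique-gene count is non-decreasing by
construction. Independent draws per size (closer to how one would run an
external assembler eight separate times) are available with
`independent = TRUE` but lose guaranteed monotonicity. The external
assembler sits behind a one-function adapter contract; the package makes
no attempt to reimplement a cDNA overlap-graph assembler. The plateau
criterion is a forward finite-difference slope falling below a
genes-per-read threshold — deliberately simple, since the original
judgment ("discovery plateaus around 1.5 M reads") was visual.

# Library comparison and GO enrichment

Two libraries are compared at equal base totals: the larger set is
truncated at a read boundary to the largest prefix not exceeding the
smaller set's base count. Reads are then mapped against the joint
assembly (e-value `1e-4`; top hit per read) and counted per contig and
sample. The headline statistic is the per-sample **maximum
reads-per-contig**: successful normalization specifically removes reads
from the most abundant transcripts, so the maximum drops.

Enrichment compares the **sample-exclusive** hit sets (ids hit by exactly
one library), per the "removing double IDs" design; each query
contributes each ancestor-closed GO term once; per term a 2×2 table of
membership against set sizes is tested with a two-sided Fisher's exact
test and adjusted by Benjamini–Hochberg across all tested terms. The
two-sided convention is "sum of all tables with point probability ≤ the
observed" (the convention of `stats::fisher.test`), with the
tail-doubling convention behind a flag; the FDR procedure is
Benjamini–Hochberg via `stats::p.adjust` — the original analysis said
only "FDR-corrected", so both choices are documented rather than claimed.
The exact q-values of the original study are not reproducible because its
FDR family size was never reported; only the bound raw p ≤ reported q is
asserted.

# In-silico isoform validation

Isogroups with exactly two isotigs whose contig paths differ by one contig
are the directly testable isoform predictions: primers flanking the
differing contig should amplify two products whose sizes differ by that
contig's length. Primer matching is exact (no mismatch model — none was
specified, and a binding-energy model would add parameters the validation
does not need); tolerance lives instead in band-size comparison, default
±10% of the predicted size, motivated by agarose-gel resolution. All
forward-site/reverse-site combinations are enumerated (the conservative
choice for multi-site primers). Band scoring is greedy nearest-match;
summary rates include the single-product false-positive rate — the
fraction of cases where multiple bands were predicted but one product
observed.

# Report rounding

Every printed ratio or percentage goes through one rounding path:
round-half-up at one decimal (`report_percent`, `report_ratio`), matching
the convention of the survey tables being reproduced; raw values are
always retained alongside. N50 uses the "first length at which the
descending cumulative base count reaches half the total" definition.
Whether a table's N50 was computed over all isotigs or the longest per
isogroup is often unstated in practice, so both scopes are provided.

# The synthetic-data generator

The generator exists to make every downstream stage testable with known
ground truth. Its model, and its deliberate simplifications:

* **Genes.** Each gene is a spliced mRNA: 5' UTR, coding exons drawn as
  stop-free codons (so the coding region translates exactly to the
  reference protein), an optional non-coding 100 bp cassette exon, and a
  3' UTR. Placing the cassette between the CDS and the 3' UTR keeps both
  isoforms translating to the same protein and makes the isoform length
  difference exactly the cassette length — the skipped-exon pattern the
  validation module looks for. Coding exon lengths are clamped to codon
  multiples.
* **Paralogs.** A pair is an original plus a copy mutated at ~10% of
  codons (protein identity ≥ 80% by construction, verified in tests).
  Both members carry the *original's* protein as their BLAST subject —
  emulating a database that contains one ortholog for a recently
  duplicated pair — which is what makes the overlap-counting rule
  observable.
* **Abundance and normalization.** Per-transcript abundances are
  log-normal (default meanlog 0, sdlog 1.5 — a realistically wide dynamic
  range). Read sampling weights are `abundance^γ`: γ = 1 is a
  non-normalized library, γ = 0 perfectly uniform. This is the simplest
  transform that reproduces the observed effect of duplex-specific
  nuclease normalization (reduced maximum reads-per-contig); the actual
  enzyme kinetics are not modeled.
* **Reads.** Lengths are normal (default mean 300 bp, sd 60 — Titanium
  chemistry scale), truncated below at 50 bp, the assembler's discard
  threshold. The start is uniform over placements that fit within the
  transcript, so very short transcripts are covered end-to-end.
  No sequencing-error model: 454 homopolymer indels and chimeras are out
  of scope, so IO-level robustness to noisy sequence is *not* exercised
  by these tests.
* **Assembly emulation.** Assembly is by read provenance, not overlap
  detection: a transcript segment becomes a contig when at least `k_min`
  reads overlap it, truncated to the covered span; a read's fate
  (contig member vs singleton) is decided by its midpoint segment, while
  its coverage extends to every segment it overlaps; expressed isoforms'
  surviving contig paths become isotigs (identical paths collapse), one
  isogroup per gene. This emulator tests downstream logic — it says
  nothing about any real assembler's behavior.
* **BLAST emulation.** Each query hits its gene's subject with exact
  coordinates of the covered coding span; e-values are rank-faithful
  stand-ins (`10^(-codons/2)`, floored at 1e-180), sufficient because
  downstream logic uses only ordering and thresholds, never e-value
  magnitudes.

Consequently, passing the synthetic-data suites demonstrates the
correctness of the counting, coordinate and statistical machinery under
the stated generative model — not performance on real 454 data, where
assembler artifacts, frameshifts, chimeras and annotation noise all enter
upstream of this package.

# Problem sizes and determinism

The test and reproduction runs use desk-scale sizes chosen to make every
property decisive yet quick: 15–60 genes, 1,200–9,000 reads per
experiment, 20 paired seeds for the normalization comparison, 10^4 random
interval systems (≤ 8 intervals) against the exhaustive partition oracle,
all 2×2 tables with totals ≤ 60 against direct hypergeometric
enumeration, and 10^3 random length lists for N50. All randomness flows
through explicit integer seeds (`withr::with_seed`), so every reported
number is bit-reproducible.

# Known limitations

* The interval-aware tally treats each query's best HSP row independently;
  multi-HSP merging per query–subject pair is not attempted.
* Extension-gain computation requires pre-oriented, ungapped plus-strand
  alignment blocks and rejects anything else rather than guessing.
* The GO layer consumes existing annotations (query→terms plus an
  ancestor table); it does not produce annotations or reduce terms by
  semantic similarity.
* Raw-read formats of the 454 platform (SFF, `.qual`) and ACE assembly
  files are not parsed; the package starts from FASTA/TSV exports.
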