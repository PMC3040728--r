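# Published counts from a 454 pyrosequencing survey of the Oncopeltus
# fasciatus ovarian and embryonic transcriptome: per-run read counts,
# assembly hierarchy sizes, annotation tallies, ortholog-hit-ratio counts
# and GO enrichment cells, as printed in the study's tables.
key	value
reads_flx_ovary_n	65394
reads_flx_embryo_n	71911
reads_titanium_n	656782
reads_titanium_nn	1293323
total_reads	2087410
reads_used	2041966
reads_assembled	1773450
reads_singleton	178770
reads_repeat	9875
reads_outlier	26943
reads_too_short	52928
n_isogroups	16617
n_isotigs	21097
n_contigs	22235
single_isotig_isogroups	14562
single_contig_isotigs	14460
isotig_n50	1735
singletons_pre_cap3	178770
cap3_contigs	28143
cap3_singlets	84388
singletons_post_cap3	112531
total_sequences	133628
isotigs_with_hits	7219
cap3_contigs_with_hits	2594
cap3_singlets_with_hits	2367
queries_with_hits	12180
nonoverlapping_same_subject	1455
overlapping_same_subject	825
unique_genes	10775
ohr_records	7219
ohr_gt_0p5	3953
ohr_gt_0p8	2689
isoform_cases	11
isoform_single_product_cases	1
go_term_a	14
go_set_a_size	750
go_term_b	1
go_set_b_size	1124
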