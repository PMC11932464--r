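# C-allele anchor coordinates (hg19) of the three CEBPB motif occurrences
# on the SOST enhancer region: ChIP-seq peak 1, ChIP-seq peak 2 and the
# rs9783823 site.
chrom	pos	label
chr17	41810515	peak1_C
chr17	41811942	peak2_C
chr17	41813369	rs9783823_C
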