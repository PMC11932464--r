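chr17	41810334	41810590	TF-ChIP:CEBPB	0	.
chr17	41811787	41812043	TF-ChIP:CEBPB	0	.
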