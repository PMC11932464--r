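# rs9783823 genotype frequencies in the EUR population (Ensembl).
genotype	freq
CC	0.155
CT	0.485
TT	0.360
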