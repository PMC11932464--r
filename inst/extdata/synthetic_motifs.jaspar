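>CEBPB_synth CEBPB-like (synthetic)
A [ 48.0 4.0 4.0 4.0 0.5 48.0 4.0 48.0 48.0 4.0 ]
C [ 4 4 4 4 5000 4 48 4 4 4 ]
G [ 4.0 4.0 4.0 48.0 0.5 4.0 4.0 4.0 4.0 4.0 ]
T [ 4.0 48.0 48.0 4.0 0.5 4.0 4.0 4.0 4.0 48.0 ]
>GFI1_synth GFI-1-like (synthetic)
A [ 35 35 35 5 5 35 5 5 ]
C [ 5 5 5 5 35 5 35 5 ]
G [ 5 5 5 5 5 5 5 5 ]
T [ 5 5 5 35 5 5 5 35 ]
>GCBOX_synth GC-box-like (synthetic)
A [ 6 6 6 6 6 6 6 6 ]
C [ 6 6 6 6 32 6 6 6 ]
G [ 32 32 32 32 6 32 32 32 ]
T [ 6 6 6 6 6 6 6 6 ]
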