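# phylogeny transversion sites (1-based)
36
39
56
73
76
94
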