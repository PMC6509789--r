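gene	log2fc
gFB	1.3
gFA1	-0.9
gNIT1	0.2
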