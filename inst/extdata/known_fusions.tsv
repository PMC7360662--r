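gene5	gene3	variants
KIAA1549	BRAF	16:9;15:9
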