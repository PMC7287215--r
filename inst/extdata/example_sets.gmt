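T1	early-response genes	GENE2	GENE4
T2	late-response genes	GENE3	GENE1
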