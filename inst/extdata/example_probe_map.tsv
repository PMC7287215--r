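probe_id	gene_id
p01	GENE1
p02	GENE1
p03	GENE2
p04	GENE2
p05	GENE3
p06	GENE4
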