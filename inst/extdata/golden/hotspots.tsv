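gene_symbol	protein_position	ref_aa	source
GENE2	12	G	hotspot
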