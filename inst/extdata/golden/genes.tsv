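gene_symbol	is_oncogene	is_tsg	in_cancer_gene_census	literature_score	drugs	chrom	span_start	span_end
GENE1	1	0	1	0.9	DRUG_A	1	101	200
GENE2	0	1	1	0.7	.	1	301	400
GENE3	0	0	0	0.2	.	1	501	600
GENE4	1	0	0	0.5	DRUG_B	1	701	800
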