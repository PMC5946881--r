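id	chrom	pos	ref	alt	gene_symbol	evidence_type	clinical_significance	evidence_level	tumor_type	drug	citation	protein_position	ref_aa
EV0001	1	150	C	T	GENE1	predictive	sensitivity	A	breast	DRUG_A	PMID:0000001	.	.
EV0002	1	320	T	G	GENE2	prognostic	poor outcome	C	colorectal	.	PMID:0000002	.	.
EV0003	.	.	.	.	GENE4	predictive	sensitivity	B	any	DRUG_B	PMID:0000003	.	.
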