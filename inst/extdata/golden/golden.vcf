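##fileformat=VCFv4.2
##INFO=<ID=CSQ,Number=.,Type=String,Description="Consequence annotations. Format: Allele|Consequence|IMPACT|SYMBOL|Feature|HGVSc|HGVSp|CANONICAL|PICK">
##contig=<ID=1,length=1200>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
1	150	.	C	T	.	PASS	CSQ=T|missense_variant|MODERATE|GENE1|TX_GENE1||p.P50L||1
1	320	.	T	G	.	PASS	CSQ=G|missense_variant|MODERATE|GENE2|TX_GENE2||p.D107E||1
1	350	.	C	A	.	PASS	CSQ=A|missense_variant|MODERATE|GENE2|TX_GENE2||p.Gly12Asp||1
1	160	.	TA	AA	.	PASS	CSQ=AA|missense_variant|MODERATE|GENE1|TX_GENE1||p.L54M||1
1	340	.	TA	T	.	PASS	CSQ=T|frameshift_variant|HIGH|GENE2|TX_GENE2||||1
1	520	.	T	C	.	PASS	CSQ=C|missense_variant|MODERATE|GENE3|TX_GENE3||||1
1	750	.	C	G	.	PASS	CSQ=G|missense_variant|MODERATE|GENE4|TX_GENE4||||1
1	540	.	T	G	.	PASS	CSQ=G|synonymous_variant|LOW|GENE3|TX_GENE3||||1
1	170	.	C	A	.	PASS	CSQ=A|synonymous_variant|LOW|GENE1|TX_GENE1||||1
1	560	.	T	A	.	PASS	CSQ=A|intron_variant|MODIFIER|GENE3|TX_GENE3||||1
1	920	.	T	C	.	PASS	CSQ=C|missense_variant|MODERATE|GENEX|TX_GENEX||||1
1	580	.	T	C	.	PASS	CSQ=C|splice_donor_variant|HIGH|GENE3|TX_GENE3||||1
1	120	.	T	G	.	LowQual	CSQ=G|missense_variant|MODERATE|GENE1|TX_GENE1||||1
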