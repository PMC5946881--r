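chrom	pos	ref	alt	tier
1	150	C	T	1
1	320	T	G	2
1	350	C	A	2
1	160	T	A	3
1	340	TA	T	3
1	520	T	C	4
1	750	C	G	3
1	540	T	G	5
1	170	C	A	5
1	560	T	A	5
1	920	T	C	4
1	580	T	C	4
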