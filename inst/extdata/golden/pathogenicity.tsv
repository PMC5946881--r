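chrom	pos	ref	alt	algorithm	score	call
1	150	C	T	sift_like	0.95	damaging
1	150	C	T	polyphen_like	0.88	damaging
1	150	C	T	cadd_like	0.4	tolerated
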