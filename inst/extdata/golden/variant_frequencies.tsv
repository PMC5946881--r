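chrom	pos	ref	alt	tumor_type	count	cohort_size
1	150	C	T	breast	42	1000
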