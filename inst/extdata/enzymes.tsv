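name	recognition	cut_offset
ClaI	ATCGAT	2
MluI	ACGCGT	1
HindIII	AAGCTT	1
BamHI	GGATCC	1
NotI	GCGGCCGC	2
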