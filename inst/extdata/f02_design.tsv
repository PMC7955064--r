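label	codon	parental
28	NNK	T
31	NNK	S
33	NNK	A
50	NNK	G
51	VTT	I
52	NNK	I
54	NNK	F
55	RGT	G
56	NNK	T
58	NNK	N
96	NNK	A
97	SCG	P
99	NNK	V
100	NNK	A
100a	NNK	R
100b	SCG	P
100c	CRT	R
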