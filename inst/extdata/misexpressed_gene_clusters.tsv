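chromosome	gene_a	fc_a	gene_b	fc_b
2	CRIM1	-3.7	FEZ2	-4.2
3	BBX	-3.8	CD47	3.4
5	CSPG2	7.2	EDIL3	4
8	ASAH1	2.4	PSD3	-9.5
10	ITGB1	3.3	NRP1	-2.5
12	WNK1	-7.5	RAB6IP2	-5.2
12	LUM	3.3	DCN	9.4
13	LMO7	-4.8	KCTD12	-4.4
13	MBNL2	-4.2	RAP2A	-3.8
16	LOC388279	3.1	MMP2	2.8
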