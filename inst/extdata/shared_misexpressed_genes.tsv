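heart_fc	fibroblast_fc	gene_symbol	chromosome
-7.4	2.4	ATP1B1	1
2.6	2.8	BRP44	1
-10.8	-2	LEPROT	1
-8.9	3.3	PPAP2B	1
4.4	-4.3	PRELP	1
-4.5	-2.3	TXNIP	1
-2.4	-1.54	ZNF281	1
23.9	1.9	CYP1B1	2
-2	2	ID2	2
2.6	11.1	PCOLCE2	3
-6.5	-1.7	ZBTB38	3
3.3	2.4	C5orf23	5
2.5	1.8	DUSP1	5
4	-38.3	EDIL3	5
3.4	-28.7	PDCD6	5
-8.5	-1.9	RHOBTB3	5
8.3	-3.5	COL12A1	6
-2.1	-1.9	RUNX1T1	8
7.7	2.1	KLF4	9
-3.8	-1.9	UGCG	9
-2.2	-1.9	C11orf54	11
10.1	-10.8	LOC387758/FIBIN	11
2.4	-1.8	C1S	12
9.7	-2.4/+2.5	DCN	12
6.1	4.1	MFAP5	12
2.6	-2	NTN4	12
-6.6	-2.3	SLC38A1	12
-6.6	2.5	KPNA3	13
4.8	2.8	LMO7	13
37.9	-4.6	POSTN	13
3.9	3.4	CHURC1	14
4	11.7	EIF2S1	14
-12.5	-2.7	IGF1R	15
4.5	19	FLJ37644	17
2.6	13.3	ID1	20
4.8	-2.4	BEX1	X
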