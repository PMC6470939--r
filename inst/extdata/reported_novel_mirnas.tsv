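mirna	c0	c1	cd1	sequence	size	mfei
cme-MIR156j-p3	27	22	52	GCTCACTTCTCTTTCTGTCAGT	22	0.90
sof-MIR156-p3	324	470	780	GCTCACTTCTCTCTCTGTCAGC	22	1.00
zma-MIR166n-p3	1179	856	835	GCTGTCGTCGACCGGAGATC	20	1.00
zma-MIR169g-p3	8	6	10	GGCGGTCTCCTTGGCTAGCC	20	1.00
zma-MIR171f-p3	30	49	41	TGATTGAGCCGTGCCAATATC	21	0.90
sbi-MIR171h-p3	18	19	10	TTGAGCCGCGTCAATATCTC	20	1.10
zma-MIR397b-p5	105	185	190	TTGAGCGCAGCGTTGATGAGC	21	0.90
PC-5p-37430_20	14	16	16	TCTCTTAAGGCTTGTTCGGA	20	0.90
PC-5p-27068_30	23	12	17	ACCGGAGGAGGTTAGAGGAGC	21	1.30
PC-5p-14301_71	41	76	65	GGTTTTAGCTTCAAGCCATCT	21	0.90
PC-5p-10912_100	30	52	52	CCGGAAATACCCAATATCTTG	21	1.00
PC-3p-7571_159	50	103	60	GGTGGCTTGTGGCTAAAACCA	21	0.90
PC-3p-65413_10	4	10	1	GCTTTAAGGGATCTGTTGGAGA	22	1.00
PC-3p-52974_13	12	8	13	AATGGTGCATTGACTTGGTC	20	1.10
PC-3p-49169_14	6	8	16	TTTGTCAATTTAAGAACTAAAA	22	1.80
PC-3p-37537_20	88	62	77	AATACTGAGCCGAATTGAAAT	21	1.10
PC-3p-33282_23	11	1	17	GCATCCATTCTTGGCTAAGTG	21	1.20
PC-3p-18761_49	21	46	43	GCCTGTATGCACTCTCGGTG	20	0.90
PC-3p-18578_50	17	22	20	TTTATGATATGTTACTCTACT	21	1.50
PC-3p-10246_108	65	7	44	CAGGCCTTCTTGGCTAAGCG	20	0.90
PC-3p-100706_6	8	8	15	GGAGCTGCAAACACTCTGGT	20	1.50
osa-MIR1430-p5	58	34	63	CTTAGCCAAGAATGGCTTGCCT	22	1.00
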