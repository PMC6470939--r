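mirna	direction	c1	cd1	log2fc	chrom	strand	start	end	hairpin_len
PC-3p-10246_108	up	7	44	2.73	chr3	+	229987606	229987776	167
PC-3p-33282_23	up	1	17	4.20	chr3	-	96704531	96704709	176
zma-miR169l-5p	up	31	107	1.77	chr1	+	298277019	298277107	87
zma-miR398a-3p	up	31	73	1.23	chr7	+	38540171	38540278	106
zma-miR398a-3p	up	31	73	1.23	chr2	+	169527758	169527897	138
zma-miR164d-3p_R+1	down	6	1	-2.47	chr7	-	172723300	172723515	214
PC-3p-74571_8	down	9	4	-1.21	chr2	+	22503757	22503904	142
PC-5p-167816_4	down	5	1	-2.21	chr8	-	103189069	103189246	135
PC-5p-395659_2	down	5	1	-2.21	chr1	+	296265246	296265464	216
PC-5p-76360_8	down	5	1	-2.21	chr1	-	52464270	52464417	103
PC-3p-65413_10	down	10	1	-3.34	chr6	+	161474760	161474953	129
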