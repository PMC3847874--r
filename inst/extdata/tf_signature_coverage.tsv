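tf	effect	regulon_size	mra_rank	mra_coverage	fdr	slr_rank	slr_coverage
PLAGL2	+	575	1	32	7.73e-25	1	20
PRRX1	-	327	4	22	2.10e-18	2	17
SPDEF	-	304	6	18	6.50e-14	3	16
SATB2	+	264	3	23	1.28e-21	4	15
ASCL2	+	537	2	28	6.12e-21	5	11
AEBP1	-	465	15	12	2.21e-05	6	10
TCF7	+	408	9	15	9.47e-09	7	9
TCEAL1	+	276	16	10	1.08e-05	7	9
HIF1A	-	371	4	22	2.58e-17	7	9
GTF2IRD1	+	429	16	10	3.34e-04	7	9
BCL6	-	455	7	16	4.50e-09	11	8
TFCP2L1	+	364	9	15	2.26e-09	14	7
FOSL2	-	421	7	16	1.70e-09	19	6
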