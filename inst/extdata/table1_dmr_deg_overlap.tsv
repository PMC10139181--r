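gene_id	gene_name	chrom	log2fc_expression	log2fc_methylation	context	region	comparison	agreement	flag
ENSECAG00000023637	ADAM33	22	-1.07	0.89	CG	Exon	4M vs 6M	Yes
ENSECAG00000009251	ATXN1	20	1.11	-0.83	CG	Exon	4M vs 6M	Yes
ENSECAG00000021591	B4GALNT1	6	-1.51	-0.87	CG	Exon	4M vs 10M	No
ENSECAG00000008566	CTSE	5	-2.63	-2.79	CHH	Exon	4M vs 6M	No
ENSECAG00000015010	CYP4F124	21	-2.69	-0.65	CG	Exon	4M vs 10M	No
ENSECAG00000015010	CYP4F124	21	-2.69	-0.55	CG	Exon	4M vs 6M	No
ENSECAG00000013832	DES	6	-1.70	1.27	CG	Exon	6M vs 10M	Yes
ENSECAG00000022980	ENTPD8	25	-3.15	-1.29	CG	Exon	4M vs 6M	No
ENSECAG00000020345	ESPN	2	1.11	1.32	CG	Exon	4M vs 10M	No *
ENSECAG00000014851	ILDR2	5	1.02	-0.64	CG	Exon	4M vs 10M	Yes
ENSECAG00000011659	KIAA1549	4	1.12	1.64	CG	Exon	4M vs 6M	No *
ENSECAG00000014702	MEDAG	17	-1.47	-2.08	CG	Exon	4M vs 10M	No
ENSECAG00000014702	MEDAG	17	-1.47	-1.84	CG	Exon	4M vs 6M	No
ENSECAG00000024536	NFE2	6	1.19	0.90	CG	Exon	4M vs 10M	No *
ENSECAG00000014030	Novel gene	3	-1.79	-2.74	CG	Exon	4M vs 10M	No
ENSECAG00000029317	AKR7A3	PJAA01003681.1	-1.97	1.68	CG	Exon	4M vs 6M	Yes
ENSECAG00000016720	OBSCN	14	-3.60	-0.35	CG	Exon	4M vs 10M	No
ENSECAG00000016720	OBSCN	14	-3.60	0.48	CG	Exon	4M vs 6M	Yes
ENSECAG00000013202	PLIN1	1	4.01	-2.73	CG	Exon	4M vs 6M	Yes
ENSECAG00000017152	RNF17	17	-2.09	0.94	CG	Exon	4M vs 10M	Yes
ENSECAG00000024853	RSPO2	9	-1.24	6.34	CHH	Exon	6M vs 10M	Yes
ENSECAG00000019227	SLC9A7	X	1.71	0.87	CG	Exon	4M vs 10M	No *
ENSECAG00000019227	SLC9A7	X	1.71	0.90	CG	Exon	4M vs 6M	No *
ENSECAG00000001372	SYN1	X	1.75	-1.13	CG	Exon	4M vs 10M	Yes
ENSECAG00000001372	SYN1	X	1.75	-1.37	CG	Exon	4M vs 6M	Yes
ENSECAG00000020605	TRIM2	2	1.10	1.16	CG	Exon	6M vs 10M	No *
ENSECAG00000007169	TTC22	2	-1.50	0.45	CG	Exon	6M vs 10M	Yes
ENSECAG00000039959	ZDBF2	18	2.35	-6.15	CHH	Exon	4M vs 10M	Yes
ENSECAG00000007090	ZFR2	7	-1.73	-0.68	CG	Exon	6M vs 10M	No
ENSECAG00000000207	ACTA1	1	-2.89	-1.33	CG	Intron	4M vs 6M	No
ENSECAG00000023637	ADAM33	22	-1.07	0.89	CG	Intron	4M vs 6M	Yes
ENSECAG00000008835	ANKRD44	18	1.49	-2.27	CG	Intron	4M vs 6M	Yes
ENSECAG00000008835	ANKRD44	18	1.61	2.10	CG	Intron	6M vs 10M	No *
ENSECAG00000020314	ANO1	12	1.90	0.56	CG	Intron	4M vs 10M	No *
ENSECAG00000020461	BMPR1A	1	1.49	-2.77	CG	Intron	4M vs 6M	Yes
ENSECAG00000009553	CADM3	5	2.07	1.01	CG	Intron	6M vs 10M	No *
ENSECAG00000010078	CIT	8	1.33	7.18	CHH	Intron	4M vs 10M	No *
ENSECAG00000010078	CIT	8	1.33	5.01	CHH	Intron	4M vs 6M	No *
ENSECAG00000016852	CPT1A	12	-1.88	0.94	CG	Intron	4M vs 10M	Yes
ENSECAG00000008566	CTSE	5	-2.63	-2.79	CHH	Intron	4M vs 6M	No
ENSECAG00000015010	CYP4F124	21	-2.69	-0.65	CG	Intron	4M vs 10M	No
ENSECAG00000015010	CYP4F124	21	-2.69	-0.55	CG	Intron	4M vs 6M	No
ENSECAG00000020795	DAGLA	12	1.28	1.02	CG	Intron	4M vs 10M	No *
ENSECAG00000006857	DCAF10	25	1.02	0.99	CG	Intron	4M vs 6M	No *
ENSECAG00000013582	DHRS3	2	-1.08	0.68	CG	Intron	4M vs 10M	Yes
ENSECAG00000019565	DLX5	4	-1.39	-1.58	CG	Intron	4M vs 10M	No
ENSECAG00000023607	DOCK5	2	1.37	0.68	CG	Intron	4M vs 6M	No *
ENSECAG00000020345	ESPN	2	1.11	1.32	CG	Intron	4M vs 10M	No *
ENSECAG00000000014	GAS6	17	-1.03	-0.82	CG	Intron	4M vs 6M	No
ENSECAG00000001312	GPR146	13	-1.18	0.74	CG	Intron	4M vs 6M	Yes
ENSECAG00000014851	ILDR2	5	1.02	-0.64	CG	Intron	4M vs 10M	Yes
ENSECAG00000014968	JMY	14	1.73	0.86	CG	Intron	4M vs 10M	No *
ENSECAG00000011659	KIAA1549	4	1.12	1.64	CG	Intron	4M vs 6M	No *
ENSECAG00000039058	KRT6C	6	-5.81	-6.16	CHH	Intron	4M vs 6M	No
ENSECAG00000020216	KRT7	6	-1.09	-2.73	CHH	Intron	4M vs 10M	No
ENSECAG00000000296	LAMC3	25	1.18	-4.45	CHH	Intron	4M vs 6M	Yes
ENSECAG00000021630	LGSN	20	-5.34	1.29	CG	Intron	4M vs 10M	Yes
ENSECAG00000021583	LMOD1	30	-1.45	1.03	CG	Intron	4M vs 6M	Yes
ENSECAG00000023118	MCC	14	1.26	-0.76	CG	Intron	4M vs 6M	Yes
ENSECAG00000024512	TNFRSF10B	2	1.26	-4.21	CHH	Intron	4M vs 10M	Yes
ENSECAG00000022376	Novel gene	18	1.52	1.66	CG	Intron	4M vs 6M	No *
ENSECAG00000022376	Novel gene	18	1.52	1.06	CG	Intron	4M vs 6M	No *
ENSECAG00000033604	SLC7A4	8	2.72	1.01	CG	Intron	4M vs 6M	No *
ENSECAG00000022376	Novel gene	18	1.09	-1.47	CG	Intron	6M vs 10M	Yes
ENSECAG00000018904	NOXA1	25	-1.77	-1.29	CG	Intron	4M vs 6M	No
ENSECAG00000016720	OBSCN	14	-3.60	-0.35	CG	Intron	4M vs 10M	No
ENSECAG00000020485	PCOLCE2	16	-1.11	-1.80	CG	Intron	6M vs 10M	No
ENSECAG00000001688	PCSK6	1	-1.36	4.83	CHH	Intron	4M vs 10M	Yes
ENSECAG00000001688	PCSK6	1	-1.36	3.39	CHH	Intron	4M vs 6M	Yes
ENSECAG00000023890	PRRX2	25	-1.11	3.56	CHH	Intron	4M vs 10M	Yes
ENSECAG00000023890	PRRX2	25	-1.11	3.37	CHH	Intron	4M vs 6M	Yes
ENSECAG00000037450	PTPRB	6	1.13	-0.61	CG	Intron	6M vs 10M	Yes
ENSECAG00000026963	PTPRR	6	-4.59	0.57	CG	Intron	4M vs 6M	Yes
ENSECAG00000009250	RAMP1	6	-1.04	1.12	CG	Intron	4M vs 10M	Yes
ENSECAG00000017152	RNF17	17	-2.09	0.94	CG	Intron	4M vs 10M	Yes
ENSECAG00000020875	RUNX2	20	1.55	0.84	CG	Intron	4M vs 10M	No *
ENSECAG00000019793	SETBP1	8	1.70	-1.03	CG	Intron	4M vs 6M	Yes
ENSECAG00000009334	SLC15A1	17	-2.27	1.62	CG	Intron	6M vs 10M	Yes
ENSECAG00000006302	SLC25A29	24	-1.29	-1.22	CG	Intron	4M vs 6M	No
ENSECAG00000014155	SMOC2	31	-1.62	1.48	CG	Intron	6M vs 10M	Yes
ENSECAG00000022037	SOX9	11	-1.91	1.26	CG	Intron	4M vs 6M	Yes
ENSECAG00000015256	SPAG9	11	1.41	1.42	CG	Intron	4M vs 10M	No *
ENSECAG00000008819	TASOR2	29	1.05	-0.94	CG	Intron	4M vs 10M	Yes
ENSECAG00000008819	TASOR2	29	1.05	-1.01	CG	Intron	4M vs 6M	Yes
ENSECAG00000008038	TENM4	7	1.03	0.74	CG	Intron	6M vs 10M	No *
ENSECAG00000007718	TMOD1	25	-2.01	-6.62	CHH	Intron	6M vs 10M	No
ENSECAG00000026887	TSPAN8	6	-1.54	-0.96	CG	Intron	6M vs 10M	No
ENSECAG00000013193	UHRF1	7	1.37	-2.17	CG	Intron	4M vs 10M	Yes
ENSECAG00000013193	UHRF1	7	1.37	-2.19	CG	Intron	4M vs 6M	Yes
ENSECAG00000022984	ZFHX3	3	1.50	1.41	CG	Intron	6M vs 10M	No *
ENSECAG00000007090	ZFR2	7	-1.73	-0.68	CG	Intron	6M vs 10M	No
ENSECAG00000024955	ZFYVE28	3	-5.29	-2.03	CG	Intron	4M vs 10M	No
ENSECAG00000016852	CPT1A	12	-1.88	1.53	CG	Promoter	4M vs 10M	Yes
ENSECAG00000013582	DHRS3	2	-1.08	0.68	CG	Promoter	4M vs 10M	Yes
ENSECAG00000012011	FBN2	14	1.43	-1.13	CG	Promoter	4M vs 10M	Yes
ENSECAG00000012011	FBN2	14	1.43	-1.16	CG	Promoter	4M vs 6M	Yes
ENSECAG00000001312	GPR146	13	-1.18	0.87	CG	Promoter	4M vs 6M	Yes
ENSECAG00000016708	HSF4	3	-1.04	1.27	CG	Promoter	4M vs 6M	Yes
ENSECAG00000016708	HSF4	3	-1.04	-1.45	CG	Promoter	6M vs 10M	No
ENSECAG00000023496	IRX3	3	-5.44	1.57	CG	Promoter	4M vs 6M	Yes
ENSECAG00000021630	LGSN	20	-5.34	1.29	CG	Promoter	4M vs 10M	Yes
ENSECAG00000013691	MALT1	8	1.55	-5.04	CHH	Promoter	4M vs 10M	Yes
ENSECAG00000033406	Novel gene	30	2.30	0.78	CG	Promoter	4M vs 10M	No	region_exception
ENSECAG00000029317	AKR7A3	PJAA01003681.1	-1.97	1.68	CG	Promoter	4M vs 6M	Yes
ENSECAG00000000991	PNMA3	X	1.68	1.41	CG	Promoter	4M vs 6M	No	region_exception
ENSECAG00000000484	PPARA	28	1.11	-1.59	CG	Promoter	4M vs 10M	Yes
ENSECAG00000024853	RSPO2	9	-1.24	6.34	CHH	Promoter	6M vs 10M	Yes
ENSECAG00000001372	SYN1	X	1.75	-1.13	CG	Promoter	4M vs 10M	Yes
ENSECAG00000001372	SYN1	X	1.75	-1.37	CG	Promoter	4M vs 6M	Yes
ENSECAG00000008819	TASOR2	29	1.05	-0.94	CG	Promoter	4M vs 10M	Yes
ENSECAG00000008819	TASOR2	29	1.05	-1.01	CG	Promoter	4M vs 6M	Yes
ENSECAG00000001072	TYMP	28	-2.34	-1.16	CG	Promoter	6M vs 10M	No
ENSECAG00000001072	TYMP	28	-2.34	-1.27	CG	Promoter	6M vs 10M	No
ENSECAG00000013202	PLIN1	1	4.01	-2.73	CG	TES	4M vs 6M	Yes
ENSECAG00000001372	SYN1	X	1.75	-1.13	CG	TSS	4M vs 10M	Yes
ENSECAG00000001372	SYN1	X	1.75	-1.37	CG	TSS	4M vs 6M	Yes
ENSECAG00000007090	ZFR2	7	-1.73	-0.68	CG	Utr3	6M vs 10M	No
ENSECAG00000029317	AKR7A3	PJAA01003681.1	-1.97	1.68	CG	Utr5	4M vs 6M	Yes
ENSECAG00000024853	RSPO2	9	-1.24	6.34	CHH	Utr5	6M vs 10M	Yes
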