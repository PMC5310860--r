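pair_id	mouse_id	mouse_sequence	human_id	human_sequence	gene_symbol
1	1504650	GPpGKNGDDGEAGKpGRpGERGPpGP	68411	PpGPpGKNGDDGEAGKpGRp	COL1A1
2	16415	KNGDDGEAGKpGRpG	41476	GPPGkNGDDGEAGKPG	COL1A1
3	1504057	KNGDDGEAGKpGRpGERGPpGP	102819	GPpGKNGDDGEAGKPGRpGERGPpGpQ	COL1A1
4	1504810	KNGDDGEAGKpGRPGERGpPGP	38011	PpGKNGDDGEAGKpG	COL1A1
5	19556	GEAGKPGRpGERGPpGP	93897	PpGKNGDDGEAGKPGRpGERGppGP	COL1A1
6	19556	GEAGKPGRpGERGPpGP	99919	PpGKNGDDGEAGKPGRpGERGppGPQ	COL1A1
7	6931	GRpGERGPpGP	87365	KNGDDGEAGKpGRpGERGPPGpQ	COL1A1
8	1504057	KNGDDGEAGKpGRpGERGPpGP	89642	KNGDDGEAGKPGRpGERGPPGpQG	COL1A1
9	7545	AGPpGPTGPTGPp	141007	ARGNDGATGAAGPpGPTGPAGppGFpGAVGAKGEAGPQGPRG	COL1A1
10	7545	AGPpGPTGPTGPp	155132	ARGNDGATGAAGpPGPTGPAGPPGFpGAVGAKGEAGpQGpRGSEGPQG	COL1A1
11	37057	NSGEpGApGNKGDTGAKGEpGATGVQGPpGP	50172	ApGSKGDTGAKGEpGPVG	COL1A1
12	18625	TGSpGSPGPDGKTGPpGP	29538	SpGSPGPDGKTGPp	COL1A1
13	18875	TGSpGSpGPDGKTGPpGP	46649	SpGSPGPDGKTGPpGPAG	COL1A1
14	20909	TGSpGSPGPDGKTGPpGPAG	46649	SpGSPGPDGKTGPpGPAG	COL1A1
15	16583	GSpGSPGPDGKTGPpGP	29538	SpGSPGPDGKTGPp	COL1A1
16	16886	GSpGSpGPDGKTGPpGP	29538	SpGSPGPDGKTGPp	COL1A1
17	19345	GSpGSpGPDGKTGPpGPAG	46649	SpGSPGPDGKTGPpGPAG	COL1A1
18	18066	SpGSPGPDGKTGPpGPAG	46649	SpGSPGPDGKTGPpGPAG	COL1A1
19	3902	KGTAGEpGKAG	117371	VMGFPGpKGAAGEPGKAGERGVpGppGAVGPAG	COL1A1
20	1506170	TAGEpGKAGERGLpGPpG	122825	GEpGKAGERGVpGPPGAVGpAGKDGEAGAQGPPGP	COL1A1
21	1506170	TAGEpGKAGERGLpGPpG	127351	AAGEPGkAGERGVpGPpGAVGPAGKDGEAGAQGPPGP	COL1A1
22	1505741	ERGEQGPAGSpG	135166	ERGEQGPAGSpGFQGLpGPAGPpGEAGKpGEQGVPGD	COL1A1
23	19814	GLPGpAGPpGEAGKpGEQ	100255	GLPGpAGppGEAGKPGEQGVPGDLGApGP	COL1A1
24	4170	KpGEQGVPGD	100255	GLPGpAGppGEAGKPGEQGVPGDLGApGP	COL1A1
25	17232	KpGEQGVpGDLGApGP	100255	GLPGpAGppGEAGKPGEQGVPGDLGApGP	COL1A1
26	16079	GQPGAKGEpGDTGVKG	92841	ADGQPGAKGEpGDAGAKGDAGPpGPAGP	COL1A1
27	26939	GQPGAKGEpGDTGVKGDAGPpGP	121241	ADGQPGAKGEpGDAGAKGDAGPpGPAGPAGPPGPIG	COL1A1
28	27161	GQpGAKGEpGDTGVKGDAGPpGP	28850	DGQPGAKGEpGDAG	COL1A1
29	27388	GQpGAKGEpGDTGVKGDAGppGP	40344	DGQPGAKGEPGDAGAK	COL1A1
30	9877	PGAKGEpGDTGVK	44802	DGQPGAKGEpGDAGAKG	COL1A1
31	14420	PGAKGEpGDTGVKGD	92841	ADGQPGAKGEpGDAGAKGDAGPpGPAGP	COL1A1
32	24239	ETGPAGRpGEVGPpGPpGPAG	140803	ETGPAGRpGEVGPpGpPGPAGEKGSPGADGPAGAPGTPGPQG	COL1A1
33	20667	GEVGPpGPpGpAGEKGSpG	140803	ETGPAGRpGEVGPpGpPGPAGEKGSPGADGPAGAPGTPGPQG	COL1A1
34	38376	ESGREGSpGAEGSpGRDGApGAKGDRGETGP	127432	GPpGESGREGAPGAEGSpGRDGSpGAKGDRGETGp	COL1A1
35	35125	REGSpGAEGSpGRDGApGAKGDRGETGP	130077	GPpGESGREGApGAEGSpGRDGSpGAKGDRGETGPA	COL1A1
36	35125	REGSpGAEGSpGRDGApGAKGDRGETGP	51175	EGSpGRDGSpGAKGDRG	COL1A1
37	10361	DGApGAKGDRGET	124886	PpGESGREGAPGAEGSpGRDGSpGAKGDRGETGP	COL1A1
38	17249	pGPVGPAGKNGDRGET	128435	DRGETGPAGPpGApGAPGAPGPVGpAGKSGDRGETGP	COL1A1
39	25169	QGIpGTGGPpGENGKpGEpGP	16910	GLpGTGGPpGENGKPGEPGp	COL3A1
40	15377	GIpGTGGPpGENGKpG	61304	GLpGTGGPpGENGKpGEPGpKG	COL3A1
41	12858	GPpGENGKpGEpGP	61304	GLpGTGGPpGENGKpGEPGpKG	COL3A1
42	31210	QNGEpGAKGERGApGEKGEGGPpGP	70911	GAPGQNGEPGGkGERGApGEKGEGGPpG	COL3A1
43	27744	GEpGAKGERGApGEKGEGGPpGP	97638	ApGEKGEGGPpG	COL3A1
44	8738	ApGEKGEGGPpGP	97638	ApGEKGEGGPpG	COL3A1
45	1505438	ApGLpGPRGIpGPAG	126318	TGAkGAAGLpGVAGApGLpGPRGIpGPVGAAGATGARG	COL1A2
46	1506234	KGEQGpAGPPGFQGLpG	138279	EVGKpGERGLHGEFGLpGpAGpRGERGPPGESGAAGP	COL1A2
47	30714	SGTTGEVGKpGERGLpGEFGLpGP	148645	EVGKpGERGLHGEFGLPGPAGpRGERGpPGESGAAGPTGPIG	COL1A2
48	27017	DGPpGRDGQpGHKGERGYpG	112515	GRDGNpGNDGPpGRDGQpGHKGERGYpG	COL1A2
49	27017	DGPpGRDGQpGHKGERGYpG	80306	NDGPpGRDGQpGHKGERGYpG	COL1A2
50	36597	PGKDGEVGPSGPVGPPGLAGERGEQGppGP	113351	GpSGpVGpPGLAGERGEQGPpGPTGFQGLPG	COL5A2
51	25768	SGNFIDQTRVLNLGPITR	53181	SGSVIDQSRVLNLGPI	UMOD
52	6864	FIDQTRVLN	43605	SVIDQSRVLNLGPI	UMOD
53	18643	IDQTRVLNLGPITR	50056	SVIDQSRVLNLGPIT	UMOD
54	16362	DQTRVLNLGPITR	50056	SVIDQSRVLNLGPIT	UMOD
55	3736	VLNLGPITR	50056	SVIDQSRVLNLGPIT	UMOD
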