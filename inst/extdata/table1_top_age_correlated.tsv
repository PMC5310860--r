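rho	adjusted_p	sequence	protein_name	start_aa	stop_aa
-0.787	3.08E-16	GSPGAKGEVGpAGSPGSNGSPGQRGEpGpQ	Collagen alpha-1(III) chain	344	373
-0.739	2.50E-13	GQpGAKGEpGDTGVKGDAGPpGP	Collagen alpha-1(I) chain	810	832
-0.680	9.48E-11	GQPGAKGEpGDTGVKGDAGPpGP	Collagen alpha-1(I) chain	810	832
-0.678	1.10E-10	ppGpAGAAGPAGNPGADGQpGAKG	Collagen alpha-1(I) chain	364	387
-0.620	2.14E-08	GLPGppGPpGEGGKQGDQ	Collagen alpha-1(I) chain	531	547
-0.582	3.34E-07	GLPGppGPpGEGGKQGDQ	Collagen alpha-1(II) chain	666	683
-0.577	4.5E-07	YKGmVGSIGAAGpPGEEGPRGppGEAG	Collagen alpha-2(IX) chain	250	276
-0.553	1.73E-06	DEAGSEAHREGETR	Fibrinogen alpha chain	527	540
-0.551	1.94E-06	KGTAGEpGKAG	Collagen alpha-1(I) chain	575	585
-0.547	2.51E-06	AGPpGPTGPTGPp	Collagen alpha-1(I) chain	320	332
0.543	2.98E-06	SLNEKLQN	Coiled-coil domain-containing protein 18	1069	1076
0.560	1.15E-06	ELQNSIIDLLNS	Kidney androgen-regulated protein	30	41
0.564	9.15E-07	VSINKELQNSII	Kidney androgen-regulated protein	25	36
0.572	5.99E-07	LVSINKELQNSIIDLLNS	Kidney androgen-regulated protein	24	41
0.597	1.15E-07	SINKELQNSIIDLLNS	Kidney androgen-regulated protein	26	41
0.599	1.07E-07	AAPEIILGNPV	Triple functional domain protein	2962	2972
0.694	2.54E-11	LVSINKELQNS	Kidney androgen-regulated protein	24	34
0.697	1.92E-11	EEHTQSPIFLGKVVDPTHK	Alpha-1-antitrypsin 1-1	395	413
0.709	6.35E-12	VSINKELQNS	Kidney androgen-regulated protein	25	34
0.717	3.00E-12	MPSLVVVSGGNSLNNLI	E3 ubiquitin-protein ligase HERC2	2846	2862
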